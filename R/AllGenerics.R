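#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' Small generic layer over the S4 slots: term, taxon and record access
#' without touching slots directly.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @return `goTerms`: character vector of canonical term ids.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("goTerms", function(x, ...) standardGeneric("goTerms"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x, ...) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x, ...) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("constraints", function(x, ...) standardGeneric("constraints"))

#' @rdname accessors
#' @export
setGeneric("generalTaxa", function(x, ...) standardGeneric("generalTaxa"))

#' @rdname accessors
#' @export
setMethod("goTerms", "OntologyGraph", function(x, ...) x@terms)

#' @rdname accessors
#' @export
setMethod("taxa", "TaxonomyTree", function(x, ...) x@nodes$taxon)

#' @rdname accessors
#' @export
setMethod("annotations", "AnnotationSet", function(x, ...) x@records)

#' @rdname accessors
#' @export
setMethod("constraints", "ConstraintSet", function(x, ...) x@records)

#' @rdname accessors
#' @export
setMethod("generalTaxa", "GeneralTaxonMap", function(x, ...) x@generalTaxa)

#' @rdname accessors
#' @export
setMethod("goTerms", "SyntheticWorld", function(x, ...) goTerms(x@ontology))

#' @describeIn accessors drop counts recorded while parsing a GAF file.
#' @export
droppedRecords <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@dropped
}

#' @describeIn accessors term name lookup (alt ids resolved).
#' @param ids character vector of term or taxon ids.
#' @export
termName <- function(x, ids) {
  stopifnot(is(x, "OntologyGraph"))
  unname(x@termName[resolveTermIds(x, ids)])
}

#' @describeIn accessors namespace lookup (alt ids resolved).
#' @export
termNamespace <- function(x, ids) {
  stopifnot(is(x, "OntologyGraph"))
  unname(x@termNamespace[resolveTermIds(x, ids)])
}

#' @describeIn accessors obsolete flag lookup (alt ids resolved).
#' @export
isObsolete <- function(x, ids) {
  stopifnot(is(x, "OntologyGraph"))
  unname(x@obsolete[resolveTermIds(x, ids)])
}

setMethod("show", "OntologyGraph", function(object) {
  ns <- table(object@termNamespace[object@terms])
  cat("OntologyGraph with", length(object@terms), "terms (",
      sum(object@obsolete), "obsolete ),",
      nrow(object@edges), "is_a/part_of edges\n")
  for (n in names(ns)) cat("  ", n, ":", ns[[n]], "\n")
})

setMethod("show", "TaxonomyTree", function(object) {
  cat("TaxonomyTree with", nrow(object@nodes), "taxa; root:",
      object@nodes$taxon[is.na(object@nodes$parent)], "\n")
  rk <- sort(table(object@nodes$rank), decreasing = TRUE)
  cat("  ranks:", paste(names(rk), rk, sep = ":", collapse = " "), "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet with", nrow(object@records), "records,",
      length(unique(object@records$protein)), "proteins,",
      length(unique(object@records$taxon)), "taxa\n")
  if (any(object@dropped > 0))
    cat("  dropped at load:",
        paste(names(object@dropped), object@dropped, sep = "=", collapse = " "), "\n")
})

setMethod("show", "GeneralTaxonMap", function(object) {
  cat("GeneralTaxonMap:", length(object@generalTaxa), "general taxa covering",
      length(object@mapping), "taxa\n")
})

setMethod("show", "ConstraintSet", function(object) {
  r <- object@records
  cat("ConstraintSet with", nrow(r), "records (",
      length(unique(r$go_id)), "terms x",
      length(unique(r$taxon_id)), "taxa )\n")
  if (nrow(r)) {
    st <- table(factor(r$state, levels = .CONSTRAINT_STATES))
    cat("  states:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@ctg), "(taxon, term) cumulative counts over",
      length(object@cg), "terms\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(goTerms(object@ontology)), "terms,",
      nrow(object@taxonomy@nodes), "taxa,",
      length(generalTaxa(object@map)), "general taxa; infeasible cells:",
      sum(!object@feasibility), "/", length(object@feasibility), "\n")
})
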
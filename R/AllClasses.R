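#' @import methods
#' @importFrom stats setNames rpois runif
#' @importFrom utils head read.delim write.table
NULL

setOldClass("igraph")

#' OntologyGraph: a Gene Ontology DAG
#'
#' Holds GO terms, their names, namespaces and obsolete flags, together with
#' the `is_a` / `part_of` edges that define the DAG. Alternative ids
#' (`alt_id`) are kept as an alias map onto canonical ids. The edge set is
#' restricted to `is_a` and `part_of`, the relations over which the true path
#' rule is asserted; `regulates`-type edges are never stored.
#'
#' @slot terms character vector of canonical term ids.
#' @slot termName named character, term id -> human-readable name.
#' @slot termNamespace named character, term id -> one of
#'   `biological_process`, `molecular_function`, `cellular_component`.
#' @slot obsolete named logical, term id -> obsolete flag.
#' @slot edges data.frame with columns `child`, `parent`, `type`
#'   (`is_a` or `part_of`).
#' @slot altMap named character, alternative id -> canonical id.
#' @slot graph igraph object with edges directed child -> parent.
#'
#' @export
setClass("OntologyGraph",
  representation(
    terms = "character",
    termName = "character",
    termNamespace = "character",
    obsolete = "logical",
    edges = "data.frame",
    altMap = "character",
    graph = "igraph"
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  trm <- object@terms
  if (anyDuplicated(trm))
    msg <- c(msg, "duplicated term ids")
  if (!all(trm %in% names(object@termNamespace)))
    msg <- c(msg, "namespace missing for some terms (namespaces must partition the term set)")
  ns <- object@termNamespace[trm]
  bad <- setdiff(unique(ns), c("biological_process", "molecular_function", "cellular_component"))
  if (length(bad))
    msg <- c(msg, paste0("unknown namespace(s): ", paste(bad, collapse = ", ")))
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(ed$type %in% c("is_a", "part_of")))
      msg <- c(msg, "edge types must be is_a or part_of")
    if (!all(c(ed$child, ed$parent) %in% trm))
      msg <- c(msg, "edges reference unknown terms")
  }
  if (igraph::vcount(object@graph) && !igraph::is_dag(object@graph))
    msg <- c(msg, "is_a/part_of graph contains a cycle")
  ## every non-root, non-obsolete term must have >= 1 parent in its namespace
  if (nrow(ed)) {
    live <- trm[!object@obsolete[trm]]
    hasParent <- live %in% ed$child
    sameNs <- ed[object@termNamespace[ed$child] == object@termNamespace[ed$parent], , drop = FALSE]
    hasNsParent <- live %in% sameNs$child
    offenders <- live[hasParent & !hasNsParent]
    if (length(offenders))
      msg <- c(msg, paste0("terms with parents but none in their own namespace: ",
                           paste(head(offenders, 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' TaxonomyTree: a rooted taxonomy with ranks
#'
#' NCBI-taxdump style tree: each taxon has a single parent (the root's parent
#' is `NA`), a rank string (possibly `"no rank"`) and a scientific name.
#'
#' @slot nodes data.frame with columns `taxon`, `parent`, `rank`, `name`;
#'   taxon ids are stored as character.
#'
#' @export
setClass("TaxonomyTree", representation(nodes = "data.frame"))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("taxon", "parent", "rank", "name")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$taxon))
    msg <- c(msg, "duplicated taxon ids")
  roots <- nd$taxon[is.na(nd$parent)]
  if (length(roots) != 1L)
    msg <- c(msg, sprintf("tree must have exactly one root, found %d", length(roots)))
  known <- nd$parent %in% nd$taxon | is.na(nd$parent)
  if (!all(known))
    msg <- c(msg, paste0("orphan taxa (parent absent): ",
                         paste(head(nd$taxon[!known], 5), collapse = ", ")))
  ## parent pointers must not cycle
  if (!length(msg)) {
    depth <- .taxDepths(nd)
    if (anyNA(depth))
      msg <- c(msg, "parent pointers contain a cycle")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: gene-product GO annotations
#'
#' GAF-derived records, already reconciled against a companion ontology and
#' taxonomy: unresolvable term or taxon ids and NOT-qualified rows are dropped
#' at parse time and only their counts are retained.
#'
#' @slot records data.frame with columns `protein`, `go_id`, `taxon`,
#'   `evidence`, `qualifier`, `db`.
#' @slot dropped named integer: counts of rows dropped while loading
#'   (`not`, `unresolved_go`, `obsolete_go`, `unresolved_taxon`).
#'
#' @export
setClass("AnnotationSet",
  representation(records = "data.frame", dropped = "integer"))

setValidity("AnnotationSet", function(object) {
  need <- c("protein", "go_id", "taxon", "evidence", "qualifier", "db")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' GeneralTaxonMap: reduction of a taxonomy to general taxa
#'
#' Maps every taxon to its most specific ancestor-or-self whose rank is
#' "class" or above (the *general taxa*). Taxa with no such ancestor map to
#' the root, which is always included among the general taxa.
#'
#' @slot generalTaxa character vector of general taxon ids.
#' @slot mapping named character, taxon id -> general taxon id.
#'
#' @export
setClass("GeneralTaxonMap",
  representation(generalTaxa = "character", mapping = "character"))

setValidity("GeneralTaxonMap", function(object) {
  m <- object@mapping
  if (!all(m %in% object@generalTaxa))
    return("mapping targets must be general taxa")
  if (!all(object@generalTaxa %in% names(m)))
    return("every general taxon must itself be mapped")
  if (!all(m[object@generalTaxa] == object@generalTaxa))
    return("general taxa must map to themselves (idempotence)")
  TRUE
})

#' ConstraintSet: taxon constraints for GO terms
#'
#' Sparse collection of per-(GO term, general taxon) constraint states.
#' Absent pairs are implicitly `neutral`.
#'
#' @slot records data.frame with columns `go_id`, `taxon_id`,
#'   `state` (one of `in`, `never_in`, `neutral`, `dubious`),
#'   `source` (one of `frequency`, `taxon_propagation`, `go_propagation`,
#'   `manual`), `n_proteins` (integer), `p_value` (numeric, `NA` if absent).
#'
#' @export
setClass("ConstraintSet", representation(records = "data.frame"))

.CONSTRAINT_STATES <- c("in", "never_in", "neutral", "dubious")
.CONSTRAINT_SOURCES <- c("frequency", "taxon_propagation", "go_propagation", "manual")

setValidity("ConstraintSet", function(object) {
  r <- object@records
  need <- c("go_id", "taxon_id", "state", "source", "n_proteins", "p_value")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(r$state %in% .CONSTRAINT_STATES))
    msg <- c(msg, "invalid state value")
  if (!all(r$source %in% .CONSTRAINT_SOURCES))
    msg <- c(msg, "invalid source value")
  if (nrow(r) && any(r$n_proteins < 0, na.rm = TRUE))
    msg <- c(msg, "n_proteins must be >= 0")
  pv <- r$p_value[!is.na(r$p_value)]
  if (length(pv) && any(pv < 0 | pv > 1))
    msg <- c(msg, "p_value must lie in [0, 1]")
  ## the same (taxon, term) must never be both "in" and "never_in"
  if (nrow(r)) {
    key <- paste(r$go_id, r$taxon_id)
    pos <- unique(key[r$state == "in"])
    neg <- unique(key[r$state == "never_in"])
    if (length(intersect(pos, neg)))
      msg <- c(msg, "a (taxon, GO term) pair is both 'in' and 'never_in'")
  }
  if (length(msg)) msg else TRUE
})

#' CountTable: cumulative annotation counts
#'
#' Distinct-protein counts that drive constraint inference. All counts are
#' cumulative over GO descendants: a protein annotated with any descendant of
#' `g` (or `g` itself) counts once towards `g`.
#'
#' @slot ctg data.frame (`taxon`, `go_id`, `c_tg`): distinct proteins of a
#'   general taxon annotated with the term or a descendant.
#' @slot cg named integer: distinct proteins annotated with the term or a
#'   descendant, over the whole annotation set.
#' @slot cAt data.frame (`namespace`, `taxon`, `c_At`): distinct proteins of
#'   the general taxon with at least one annotation in the sub-ontology.
#' @slot cA named integer: distinct proteins with at least one annotation in
#'   the sub-ontology, over the whole annotation set.
#' @slot nsMap named character, term id -> namespace.
#'
#' @export
setClass("CountTable",
  representation(ctg = "data.frame", cg = "integer", cAt = "data.frame",
                 cA = "integer", nsMap = "character"))

#' SyntheticWorld: a generated benchmark universe
#'
#' A self-contained ontology + taxonomy + ground-truth feasibility world for
#' testing constraint inference. Feasibility is consistent with the true path
#' rule by construction: infeasibility is planted on whole
#' (taxonomy subtree x GO sub-DAG) blocks, so it is down-closed over GO
#' descendants and taxonomy descendants, and feasibility is up-closed over GO
#' ancestors.
#'
#' @slot ontology OntologyGraph.
#' @slot taxonomy TaxonomyTree.
#' @slot map GeneralTaxonMap for the taxonomy.
#' @slot feasibility logical matrix, rows = general taxa, cols = term ids.
#' @slot params list of generation parameters (sizes, fractions, seed).
#'
#' @export
setClass("SyntheticWorld",
  representation(ontology = "OntologyGraph", taxonomy = "TaxonomyTree",
                 map = "GeneralTaxonMap", feasibility = "matrix",
                 params = "list"))

setValidity("SyntheticWorld", function(object) {
  f <- object@feasibility
  if (!is.logical(f)) return("feasibility must be a logical matrix")
  if (!all(rownames(f) %in% generalTaxa(object@map)))
    return("feasibility rows must be general taxa")
  if (!all(colnames(f) %in% goTerms(object@ontology)))
    return("feasibility columns must be ontology terms")
  TRUE
})
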
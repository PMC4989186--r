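#' @include AllClasses.R utils.R
NULL

#' Parse a GAF 2.1/2.2 annotation file
#'
#' Loads annotation rows into an [AnnotationSet-class], reconciling them
#' against a companion ontology and taxonomy:
#' * rows whose qualifier contains `NOT` are excluded (negated assertions
#'   must not feed constraint inference),
#' * GO ids are resolved through `alt_id` aliases; unresolvable or obsolete
#'   ids are dropped,
#' * taxon ids absent from the taxonomy are dropped,
#' * multi-organism taxon fields (`taxon:X|taxon:Y`) keep the first entry,
#'   the annotated organism by GOA convention.
#' Drop counts are retained and available via [droppedRecords()].
#'
#' @param file path (plain or gzip), connection, or GAF text.
#' @param ontology an [OntologyGraph-class].
#' @param taxonomy a [TaxonomyTree-class].
#' @param evidenceInclude,evidenceExclude optional character vectors of
#'   evidence codes to keep or drop (include applied first).
#' @return an [AnnotationSet-class].
#' @export
parseGAF <- function(file, ontology, taxonomy,
                     evidenceInclude = NULL, evidenceExclude = NULL) {
  lines <- .readInputLines(file)
  keep <- !grepl("^!", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  dropped <- c(not = 0L, unresolved_go = 0L, obsolete_go = 0L,
               unresolved_taxon = 0L)
  if (!length(lines))
    return(new("AnnotationSet", records = .emptyGafRecords(), dropped = dropped))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 13L
  if (any(bad))
    stop("GAF format error: fewer than 13 columns at line ", lineNo[bad][1])

  db <- vapply(fields, `[`, "", 1L)
  objId <- vapply(fields, `[`, "", 2L)
  qualifier <- vapply(fields, `[`, "", 4L)
  goId <- vapply(fields, `[`, "", 5L)
  evidence <- vapply(fields, `[`, "", 7L)
  taxField <- vapply(fields, `[`, "", 13L)

  isNot <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                  function(q) any(q == "NOT"), logical(1))
  dropped["not"] <- sum(isNot)
  ok <- !isNot

  resolved <- resolveTermIds(ontology, goId)
  unres <- ok & is.na(resolved)
  dropped["unresolved_go"] <- sum(unres)
  ok <- ok & !is.na(resolved)
  obs <- ok & isObsolete(ontology, resolved)
  obs[is.na(obs)] <- FALSE
  dropped["obsolete_go"] <- sum(obs, na.rm = TRUE)
  ok <- ok & !obs

  taxon <- sub("\\|.*$", "", taxField)       # first organism only
  taxon <- sub("^taxon:", "", taxon)
  knownTax <- taxon %in% taxa(taxonomy)
  dropped["unresolved_taxon"] <- sum(ok & !knownTax)
  ok <- ok & knownTax

  rec <- data.frame(protein = objId[ok], go_id = resolved[ok],
                    taxon = taxon[ok], evidence = evidence[ok],
                    qualifier = qualifier[ok], db = db[ok],
                    stringsAsFactors = FALSE)
  if (!is.null(evidenceInclude))
    rec <- rec[rec$evidence %in% evidenceInclude, , drop = FALSE]
  if (!is.null(evidenceExclude))
    rec <- rec[!(rec$evidence %in% evidenceExclude), , drop = FALSE]
  rownames(rec) <- NULL
  new("AnnotationSet", records = rec, dropped = dropped)
}

.emptyGafRecords <- function() {
  data.frame(protein = character(), go_id = character(), taxon = character(),
             evidence = character(), qualifier = character(), db = character(),
             stringsAsFactors = FALSE)
}

#' Write an AnnotationSet as GAF 2.1 text
#'
#' @param x an [AnnotationSet-class].
#' @param file optional output path.
#' @return character vector of GAF lines, invisibly.
#' @export
writeGAF <- function(x, file = NULL) {
  r <- x@records
  body <- paste(r$db, r$protein, r$protein, r$qualifier, r$go_id,
                "PMID:0000000", r$evidence, "", "P", "", "", "protein",
                paste0("taxon:", r$taxon), "20160101", r$db, "", "",
                sep = "\t")
  out <- c("!gaf-version: 2.1", body)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
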
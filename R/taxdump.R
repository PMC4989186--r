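#' @include AllClasses.R utils.R
NULL

.splitDmp <- function(lines) {
  ## taxdump rows end in "\t|" and fields are separated by "\t|\t"
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Parse an NCBI taxdump taxonomy
#'
#' Reads `nodes.dmp` (taxon, parent, rank) and `names.dmp` (scientific names
#' only; synonyms and other name classes are ignored) into a
#' [TaxonomyTree-class]. The NCBI convention of the root being its own parent
#' is translated into a `NA` parent.
#'
#' @param nodesFile path/connection/text for `nodes.dmp`.
#' @param namesFile path/connection/text for `names.dmp`; optional — absent
#'   names default to the taxon id.
#' @return a [TaxonomyTree-class].
#' @export
parseTaxdump <- function(nodesFile, namesFile = NULL) {
  nl <- .readInputLines(nodesFile)
  nl <- nl[nzchar(nl)]
  fields <- .splitDmp(nl)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("taxdump format error in nodes.dmp at line ", which(short)[1])
  taxon <- trimws(vapply(fields, `[`, "", 1L))
  parent <- trimws(vapply(fields, `[`, "", 2L))
  rank <- trimws(vapply(fields, `[`, "", 3L))

  selfLoop <- taxon == parent
  rootCandidates <- taxon[selfLoop]
  if (length(rootCandidates) != 1L) {
    ## any non-root self-parent (or several roots) is an integrity problem
    stop("taxdump integrity error: expected exactly one self-parented root, found ",
         length(rootCandidates),
         if (length(rootCandidates)) paste0(" (", paste(head(rootCandidates, 5), collapse = ", "), ")"))
  }
  parent[selfLoop] <- NA_character_

  orphans <- taxon[!is.na(parent) & !(parent %in% taxon)]
  if (length(orphans))
    stop("taxdump integrity error: orphan taxa with absent parents: ",
         paste(head(orphans, 10), collapse = ", "))

  nm <- setNames(rep(NA_character_, length(taxon)), taxon)
  if (!is.null(namesFile)) {
    ml <- .readInputLines(namesFile)
    ml <- ml[nzchar(ml)]
    nf <- .splitDmp(ml)
    keep <- lengths(nf) >= 4L
    tax <- trimws(vapply(nf[keep], `[`, "", 1L))
    txt <- trimws(vapply(nf[keep], `[`, "", 2L))
    cls <- trimws(vapply(nf[keep], `[`, "", 4L))
    sci <- cls == "scientific name"
    nm[tax[sci]] <- txt[sci]
  }
  nm[is.na(nm)] <- names(nm)[is.na(nm)]

  new("TaxonomyTree",
      nodes = data.frame(taxon = taxon, parent = parent, rank = rank,
                         name = unname(nm), stringsAsFactors = FALSE))
}

#' Write a taxonomy in taxdump dialect
#'
#' Emits `nodes.dmp` / `names.dmp` text that [parseTaxdump()] reads back.
#'
#' @param x a [TaxonomyTree-class].
#' @param nodesFile,namesFile optional output paths.
#' @return list with character vectors `nodes` and `names`, invisibly.
#' @export
writeTaxdump <- function(x, nodesFile = NULL, namesFile = NULL) {
  nd <- x@nodes
  parent <- ifelse(is.na(nd$parent), nd$taxon, nd$parent)  # root self-loop
  nodes <- paste(nd$taxon, parent, nd$rank, sep = "\t|\t")
  nodes <- paste0(nodes, "\t|")
  nms <- paste(nd$taxon, nd$name, "", "scientific name", sep = "\t|\t")
  nms <- paste0(nms, "\t|")
  if (!is.null(nodesFile)) writeLines(nodes, nodesFile)
  if (!is.null(namesFile)) writeLines(nms, namesFile)
  invisible(list(nodes = nodes, names = nms))
}
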
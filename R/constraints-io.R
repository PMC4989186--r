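#' @include AllClasses.R utils.R
NULL

#' Read and write taxon-constraint tables
#'
#' The native TSV dialect has a fixed column order
#' `go_id, taxon_id, state, source, n_proteins, p_value`; an absent p-value
#' is an empty field. `readConstraints(writeConstraints(x))` is lossless.
#'
#' @param x a [ConstraintSet-class].
#' @param file path (plain or gzip), connection, or text.
#' @return `readConstraints`: a [ConstraintSet-class];
#'   `writeConstraints`: the TSV lines, invisibly.
#' @export
writeConstraints <- function(x, file = NULL) {
  r <- constraints(x)
  pv <- ifelse(is.na(r$p_value), "", format(r$p_value, digits = 17, scientific = TRUE, trim = TRUE))
  out <- c(paste(c("go_id", "taxon_id", "state", "source", "n_proteins", "p_value"),
                 collapse = "\t"),
           if (nrow(r)) paste(r$go_id, r$taxon_id, r$state, r$source,
                              r$n_proteins, pv, sep = "\t"))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @rdname writeConstraints
#' @export
readConstraints <- function(file) {
  lines <- .readInputLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]][1:2],
                                   c("go_id", "taxon_id")))
    stop("constraint TSV format error: missing header")
  lines <- lines[-1]
  if (!length(lines))
    return(constraintSet(.emptyConstraintRecords()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 5L
  if (any(bad))
    stop("constraint TSV format error at data line ", which(bad)[1])
  state <- vapply(f, `[`, "", 3L)
  unknown <- setdiff(unique(state), .CONSTRAINT_STATES)
  if (length(unknown))
    stop("constraint TSV format error: unknown state token '", unknown[1], "'")
  pv <- vapply(f, function(z) if (length(z) >= 6L) z[6L] else "", "")
  rec <- data.frame(
    go_id = vapply(f, `[`, "", 1L),
    taxon_id = vapply(f, `[`, "", 2L),
    state = state,
    source = vapply(f, `[`, "", 4L),
    n_proteins = as.integer(vapply(f, `[`, "", 5L)),
    p_value = ifelse(nzchar(pv), suppressWarnings(as.numeric(pv)), NA_real_),
    stringsAsFactors = FALSE)
  constraintSet(rec)
}

.emptyConstraintRecords <- function() {
  data.frame(go_id = character(), taxon_id = character(), state = character(),
             source = character(), n_proteins = integer(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' Construct a ConstraintSet from a record data.frame
#'
#' Missing `n_proteins` / `p_value` columns are filled with `0` / `NA`.
#'
#' @param records data.frame with at least `go_id`, `taxon_id`, `state`,
#'   `source` columns.
#' @return a [ConstraintSet-class].
#' @export
constraintSet <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$n_proteins)) records$n_proteins <- rep(0L, nrow(records))
  if (is.null(records$p_value)) records$p_value <- rep(NA_real_, nrow(records))
  records$n_proteins <- as.integer(records$n_proteins)
  rownames(records) <- NULL
  new("ConstraintSet",
      records = records[, c("go_id", "taxon_id", "state", "source",
                            "n_proteins", "p_value"), drop = FALSE])
}

#' Parse a GO-consortium style taxon-constraint file
#'
#' TSV triples `go_id, relation, taxon_id` where the relation is
#' `only_in_taxon` (the term may annotate only that taxon and its
#' descendants) or `never_in_taxon` (the term is forbidden for the taxon and
#' its descendants). `only_in` / `never_in` are accepted as synonyms. A
#' header line is optional.
#'
#' @param file path (plain or gzip), connection, or text.
#' @return data.frame with columns `go_id`, `relation`
#'   (`only_in` / `never_in`), `taxon_id`.
#' @export
parseGOCConstraints <- function(file) {
  lines <- .readInputLines(file)
  lines <- lines[nzchar(lines) & !grepl("^[#!]", lines)]
  empty <- data.frame(go_id = character(), relation = character(),
                      taxon_id = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f) && tolower(f[[1]][1]) %in% c("go_id", "go-id", "goid"))
    f <- f[-1]
  if (!length(f)) return(empty)
  bad <- lengths(f) < 3L
  if (any(bad))
    stop("constraint triple format error at line ", which(bad)[1])
  rel <- vapply(f, `[`, "", 2L)
  rel <- sub("_taxon$", "", rel)
  unknown <- setdiff(unique(rel), c("only_in", "never_in"))
  if (length(unknown))
    stop("constraint triple format error: unknown relation '", unknown[1], "'")
  data.frame(go_id = vapply(f, `[`, "", 1L),
             relation = rel,
             taxon_id = vapply(f, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
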
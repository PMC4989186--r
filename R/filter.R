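#' @include AllClasses.R utils.R propagation.R
NULL

#' Read a similarity hit table
#'
#' Tab-separated hits, BLAST `outfmt 6` compatible: with 12 or more columns
#' the standard layout is assumed and columns 1 (query), 2 (subject) and
#' 11 (e-value) are used; with exactly 3 columns they are taken as
#' (query, subject, e-value) directly.
#'
#' @param file path (plain or gzip), connection, or text.
#' @return data.frame (`query`, `subject`, `evalue`).
#' @export
readHitTable <- function(file) {
  lines <- .readInputLines(file)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines))
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(f)
  eCol <- ifelse(nc >= 11L, 11L, 3L)
  if (any(nc < 3L))
    stop("hit table format error at line ", which(nc < 3L)[1])
  data.frame(query = vapply(f, `[`, "", 1L),
             subject = vapply(f, `[`, "", 2L),
             evalue = as.numeric(mapply(function(z, i) z[i], f, eCol)),
             stringsAsFactors = FALSE)
}

#' @rdname readHitTable
#' @param hits data.frame (`query`, `subject`, `evalue`).
#' @export
writeHitTable <- function(hits, file = NULL) {
  out <- paste(hits$query, hits$subject,
               format(hits$evalue, digits = 6, scientific = TRUE, trim = TRUE),
               sep = "\t")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

## e-value -> score; e-values below 1e-180 (including 0) score as 180
.SCORE_CAP <- 180
.hitScore <- function(e) pmin(-log10(pmax(e, 10^(-.SCORE_CAP))), .SCORE_CAP)

#' Transfer GO terms from similarity hits
#'
#' Annotation transfer by homology: for each query, hits whose subject
#' belongs to the excluded clade are dropped, the first `k` remaining hits
#' (by ascending e-value) are kept, and every GO term annotated to a
#' surviving subject contributes with score `-log10(e-value)` (capped at
#' 180). The result is the non-redundant term set with, per term, the
#' maximum score over all occurrences and the number of distinct
#' contributing subjects. Ancestor closure is deliberately *not* applied
#' here; it happens at evaluation time.
#'
#' @param hits data.frame (`query`, `subject`, `evalue`).
#' @param annotations an [AnnotationSet-class] supplying subject GO terms
#'   and subject taxa.
#' @param taxonomy a [TaxonomyTree-class] (for clade exclusion).
#' @param k hits retained per query after exclusion (default 100).
#' @param excludeClade optional taxon id: subjects inside this clade are
#'   removed before truncation.
#' @return data.frame (`go_id`, `score`, `n_subjects`) — the prediction
#'   table.
#' @export
transferFromHits <- function(hits, annotations, taxonomy, k = 100,
                             excludeClade = NULL) {
  rec <- annotations(annotations)
  protTaxon <- rec$taxon[match(hits$subject, rec$protein)]
  keep <- !is.na(protTaxon)
  if (!is.null(excludeClade)) {
    clade <- taxDescendants(taxonomy, excludeClade)
    keep <- keep & !(protTaxon %in% clade)
  }
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    ## first k hits per query by ascending e-value
    o <- order(h$query, h$evalue)
    h <- h[o, , drop = FALSE]
    within <- stats::ave(seq_len(nrow(h)), h$query, FUN = seq_along)
    h <- h[within <= k, , drop = FALSE]
  }
  if (!nrow(h))
    return(data.frame(go_id = character(), score = numeric(),
                      n_subjects = integer(), stringsAsFactors = FALSE))
  byProt <- split(rec$go_id, rec$protein)
  termLists <- byProt[h$subject]
  nT <- lengths(termLists)
  dt <- data.table(go_id = unlist(termLists, use.names = FALSE),
                   subject = rep(h$subject, nT),
                   score = .hitScore(rep(h$evalue, nT)))
  out <- dt[, .(score = max(score), n_subjects = uniqueN(subject)), by = go_id]
  out <- as.data.frame(out[order(go_id)])
  out$n_subjects <- as.integer(out$n_subjects)
  out
}

#' Filter predictions with taxon constraints
#'
#' Removes predicted terms that are taxonomically incompatible with the
#' target: `never_in` terms are removed under both world hypotheses;
#' `neutral` (and `dubious`, which means "no decision was made") terms are
#' kept under the open-world hypothesis and removed under the closed-world
#' one; `in` terms are always kept. With `backoff = TRUE` a banned
#' (`never_in`) term is replaced by its nearest ancestor that is not banned
#' for the target, keeping the term's score.
#'
#' @param preds prediction table from [transferFromHits()].
#' @param set a [ConstraintSet-class].
#' @param map a [GeneralTaxonMap-class].
#' @param targetTaxon the taxon being annotated (resolved through the map).
#' @param world `"open"` or `"closed"`.
#' @param ontology optional [OntologyGraph-class]; needed for `backoff` and
#'   to warn on terms absent from the ontology (treated as neutral).
#' @param backoff replace banned terms by their nearest allowed ancestor.
#' @return the filtered prediction table; removed rows are attached as
#'   `attr(, "removed")` with their state.
#' @export
applyConstraints <- function(preds, set, map, targetTaxon,
                             world = c("open", "closed"),
                             ontology = NULL, backoff = FALSE) {
  world <- match.arg(world)
  if (!nrow(preds)) {
    attr(preds, "removed") <- cbind(preds, state = character())
    return(preds)
  }
  go <- preds$go_id
  if (!is.null(ontology)) {
    res <- resolveTermIds(ontology, go)
    if (anyNA(res))
      warning("predicted term(s) absent from the ontology, treated as neutral: ",
              paste(head(go[is.na(res)], 5), collapse = ", "))
    go[!is.na(res)] <- res[!is.na(res)]
  }
  st <- lookupConstraint(set, map, targetTaxon, go)
  st[st == "dubious"] <- "neutral"
  keep <- if (world == "open") st != "never_in" else st == "in"
  removed <- cbind(preds[!keep, , drop = FALSE], state = st[!keep])
  out <- preds[keep, , drop = FALSE]
  if (backoff && !is.null(ontology)) {
    banned <- preds[st == "never_in", , drop = FALSE]
    for (i in seq_len(nrow(banned))) {
      sub <- .nearestAllowedAncestor(banned$go_id[i], set, map, targetTaxon,
                                     ontology)
      if (is.na(sub)) next
      j <- match(sub, out$go_id)
      if (is.na(j)) {
        out <- rbind(out, data.frame(go_id = sub, score = banned$score[i],
                                     n_subjects = banned$n_subjects[i]))
      } else {
        out$score[j] <- max(out$score[j], banned$score[i])
      }
    }
    out <- out[order(out$go_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

## breadth-first walk up the DAG for the closest non-banned ancestor;
## ties at equal depth break on the smaller term id
.nearestAllowedAncestor <- function(go, set, map, targetTaxon, ontology) {
  frontier <- go
  seen <- character()
  repeat {
    parents <- unique(ontology@edges$parent[ontology@edges$child %in% frontier])
    parents <- setdiff(parents, seen)
    if (!length(parents)) return(NA_character_)
    st <- lookupConstraint(set, map, rep(targetTaxon, length(parents)), parents)
    ok <- parents[st != "never_in"]
    if (length(ok)) return(sort(ok)[1])
    seen <- c(seen, parents)
    frontier <- parents
  }
}

#' GO-centric evaluation against a gold standard
#'
#' Both the predicted and the gold term sets are replaced by their ancestor
#' closures over `is_a`/`part_of` (roots included). Each closed predicted
#' term inherits the maximum score of the descendants that produced it
#' (including itself when predicted directly), is assigned to a score bin,
#' and counts as a true positive iff it lies in the closed gold set.
#'
#' @param preds prediction table (`go_id`, `score`).
#' @param gold character vector of gold-standard term ids.
#' @param ontology an [OntologyGraph-class].
#' @param bins increasing numeric vector of bin edges covering the observed
#'   scores.
#' @return data.frame (`bin_low`, `bin_high`, `tp`, `fp`).
#' @export
evaluateGOCentric <- function(preds, gold, ontology, bins) {
  stopifnot(length(bins) >= 2, !is.unsorted(bins))
  empty <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                      tp = 0L, fp = 0L)
  if (!nrow(preds)) return(empty)
  if (!length(gold))
    warning("empty gold standard: every prediction is a false positive")
  ## duplicate predictions collapse to their max score first
  dt <- data.table(go_id = resolveTermIds(ontology, preds$go_id),
                   score = preds$score)
  dt <- dt[!is.na(go_id), .(score = max(score)), by = go_id]
  anc <- .ancestorList(ontology, dt$go_id)
  closure <- data.table(go_id = unlist(anc[dt$go_id], use.names = FALSE),
                        score = rep(dt$score, lengths(anc[dt$go_id])))
  closure <- closure[, .(score = max(score)), by = go_id]
  goldClosed <- termAncestors(ontology, gold, includeSelf = TRUE)
  closure[, tp := go_id %in% goldClosed]
  bin <- findInterval(closure$score, bins, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- empty
  tpTab <- tapply(closure$tp, factor(bin, levels = seq_len(nrow(empty))), sum)
  nTab <- tapply(rep(1L, nrow(closure)),
                 factor(bin, levels = seq_len(nrow(empty))), sum)
  tpTab[is.na(tpTab)] <- 0; nTab[is.na(nTab)] <- 0
  out$tp <- as.integer(tpTab)
  out$fp <- as.integer(nTab - tpTab)
  out
}
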
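#' @include AllClasses.R utils.R counts.R
NULL

## evidence codes treated as manually-curated / experimental support
.EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                         "HTP", "HDA", "HMP", "HGI", "HEP", "TAS", "IC")

#' Experimental-evidence view of an annotation set
#'
#' The (general taxon, term) pairs backed by at least one experimentally
#' evidenced annotation of the term *or one of its descendants*.
#'
#' @param annotations an [AnnotationSet-class].
#' @param ontology an [OntologyGraph-class].
#' @param map a [GeneralTaxonMap-class].
#' @param codes evidence codes counted as experimental.
#' @return data.frame (`taxon`, `go_id`) of supported pairs.
#' @export
experimentalPairs <- function(annotations, ontology, map,
                              codes = .EXPERIMENTAL_CODES) {
  rec <- annotations(annotations)
  rec <- rec[rec$evidence %in% codes, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(taxon = character(), go_id = character(),
                      stringsAsFactors = FALSE))
  gen <- toGeneral(map, rec$taxon)
  anc <- .ancestorList(ontology, unique(rec$go_id))
  nAnc <- lengths(anc)[rec$go_id]
  out <- unique(data.frame(
    taxon = rep(gen, nAnc),
    go_id = unlist(anc[rec$go_id], use.names = FALSE),
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

.polarityTransform <- function(p) (p - 1) / (p + 1)

#' Assign polarities to (robust taxon, frequent term) pairs
#'
#' Maps relative probabilities into `[-1, +1]` with the monotone transform
#' `pol = (P_rel - 1) / (P_rel + 1)` and labels each pair:
#' * `positive` when `pol >= thetaPos` (default +0.2),
#' * `negative` when `pol <= thetaNeg` (default -0.6),
#' * `neutral`  otherwise.
#'
#' Zero-count policy: when no protein of the taxon carries the term
#' (`c_tg = 0`), a robust — hence well-studied — taxon is treated under the
#' closed-world assumption and labelled `negative` (polarity -1); a
#' non-robust taxon stays `neutral` (open world). Any experimentally
#' evidenced annotation of the term or a descendant in the taxon forces the
#' label to `positive` regardless of frequency.
#'
#' @param counts a [CountTable-class].
#' @param frequent character vector of frequent term ids (see
#'   [selectFrequentTerms()]).
#' @param robust character vector of robust general taxa.
#' @param experimental data.frame (`taxon`, `go_id`) from
#'   [experimentalPairs()], or `NULL`.
#' @param thetaNeg,thetaPos label thresholds, `thetaNeg < thetaPos`.
#' @param extraTaxa additional (non-robust) general taxa to score under the
#'   open-world rule; empty by default.
#' @return data.frame (`taxon`, `go_id`, `p_rel`, `polarity`, `label`,
#'   `n_proteins`, `has_experimental`) — the polarity table.
#' @export
assignPolarity <- function(counts, frequent, robust, experimental = NULL,
                           thetaNeg = -0.6, thetaPos = 0.2,
                           extraTaxa = character()) {
  if (!(thetaNeg < thetaPos))
    stop("configuration error: thetaNeg must be < thetaPos")
  taxAll <- c(robust, setdiff(extraTaxa, robust))
  grid <- expand.grid(taxon = taxAll, go_id = frequent,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) {
    grid$p_rel <- numeric(); grid$polarity <- numeric()
    grid$label <- character(); grid$n_proteins <- integer()
    grid$has_experimental <- logical()
    return(grid)
  }
  grid$n_proteins <- .lookupCtg(counts, grid$taxon, grid$go_id)
  grid$p_rel <- relativeProbability(counts, grid$taxon, grid$go_id)
  grid$polarity <- .polarityTransform(grid$p_rel)
  isRobust <- grid$taxon %in% robust
  zero <- grid$n_proteins == 0L | !is.finite(grid$polarity)
  grid$polarity[zero & isRobust] <- -1
  grid$polarity[zero & !isRobust] <- 0
  grid$label <- ifelse(grid$polarity >= thetaPos, "positive",
                ifelse(grid$polarity <= thetaNeg, "negative", "neutral"))
  grid$label[zero & !isRobust] <- "neutral"
  grid$has_experimental <- FALSE
  if (!is.null(experimental) && nrow(experimental)) {
    hit <- paste(grid$taxon, grid$go_id) %in%
           paste(experimental$taxon, experimental$go_id)
    grid$has_experimental <- hit
    grid$label[hit] <- "positive"
    grid$polarity[hit] <- 1
  }
  rownames(grid) <- NULL
  grid
}

#' Bootstrap p-values for seed polarities
#'
#' Statistical support for each (taxon, term) label: the proteins of the
#' taxon are resampled with replacement `nReps` times (the protein is the
#' resampling unit — all its annotations move together, and a protein drawn
#' twice counts twice), the label is recomputed under the same rule with
#' global counts held fixed, and the p-value is the fraction of replicates
#' whose label differs from the original. Identical seed and inputs give
#' identical p-values.
#'
#' @param annotations the [AnnotationSet-class] the polarities came from.
#' @param polarity a polarity table from [assignPolarity()].
#' @param counts the matching [CountTable-class].
#' @param ontology an [OntologyGraph-class].
#' @param map a [GeneralTaxonMap-class].
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param thetaNeg,thetaPos the thresholds used for the original labels.
#' @param codes experimental evidence codes.
#' @return the polarity table with a `p_value` column appended (`NA` for a
#'   taxon with no proteins).
#' @export
bootstrapPvalues <- function(annotations, polarity, counts, ontology, map,
                             nReps = 100, seed = 1,
                             thetaNeg = -0.6, thetaPos = 0.2,
                             codes = .EXPERIMENTAL_CODES) {
  stopifnot(nReps >= 1)
  rec <- annotations(annotations)
  gen <- toGeneral(map, rec$taxon)
  polarity$p_value <- NA_real_
  .withSeed(seed, {
    for (t in unique(polarity$taxon)) {
      sel <- polarity$taxon == t
      gTerms <- polarity$go_id[sel]
      sub <- rec[gen == t, , drop = FALSE]
      prot <- unique(sub$protein)
      nP <- length(prot)
      if (nP == 0L) next
      ## ancestor-closed membership matrices: proteins x terms-of-interest
      anc <- .ancestorList(ontology, unique(sub$go_id))
      pi <- match(sub$protein, prot)
      nAnc <- lengths(anc)[sub$go_id]
      pairP <- rep(pi, nAnc)
      pairG <- match(unlist(anc[sub$go_id], use.names = FALSE), gTerms)
      keep <- !is.na(pairG)
      M <- matrix(0L, nP, length(gTerms))
      M[cbind(pairP[keep], pairG[keep])] <- 1L
      isExp <- sub$evidence %in% codes
      E <- matrix(0L, nP, length(gTerms))
      if (any(isExp)) {
        nAncE <- nAnc[isExp]
        eP <- rep(pi[isExp], nAncE)
        eG <- match(unlist(anc[sub$go_id[isExp]], use.names = FALSE), gTerms)
        keepE <- !is.na(eG)
        E[cbind(eP[keepE], eG[keepE])] <- 1L
      }
      ## namespace membership for c_At (direct annotations define membership)
      nsTerm <- unname(counts@nsMap[gTerms])
      nsLevels <- unique(nsTerm)
      N <- matrix(0L, nP, length(nsLevels))
      dns <- match(unname(counts@nsMap[sub$go_id]), nsLevels)
      okn <- !is.na(dns)
      N[cbind(pi[okn], dns[okn])] <- 1L
      nsIdx <- match(nsTerm, nsLevels)

      cg <- unname(counts@cg[gTerms])
      cA <- unname(counts@cA[nsTerm])
      orig <- polarity$label[sel]
      diffCount <- numeric(length(gTerms))
      for (r in seq_len(nReps)) {
        w <- tabulate(sample.int(nP, nP, replace = TRUE), nP)
        ctg <- as.vector(w %*% M)
        hasExp <- as.vector(w %*% E) > 0
        cAt <- as.vector(w %*% N)[nsIdx]
        p <- (ctg / cAt) / (cg / cA)
        pol <- .polarityTransform(p)
        pol[ctg == 0 | !is.finite(pol)] <- -1   # robust closed world
        lab <- ifelse(pol >= thetaPos, "positive",
               ifelse(pol <= thetaNeg, "negative", "neutral"))
        lab[hasExp] <- "positive"
        diffCount <- diffCount + (lab != orig)
      }
      polarity$p_value[sel] <- diffCount / nReps
    }
  })
  polarity
}
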
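#' @include AllClasses.R utils.R reduction.R
#' @import data.table
NULL

#' Cumulative term counts per general taxon
#'
#' Computes the distinct-protein association counts that drive inference,
#' cumulative over GO descendants: a protein annotated with any term in the
#' `is_a`/`part_of` descendant closure of `g` (including `g` itself) counts
#' once towards `g`. Concretely, for sub-ontology `A`, general taxon `t` and
#' term `g`:
#' * `c_tg`: distinct proteins of `t` annotated with `g` or a descendant,
#' * `c_g`:  distinct proteins so annotated anywhere in the set,
#' * `c_At`: distinct proteins of `t` with at least one annotation in `A`,
#' * `c_A`:  distinct proteins with at least one annotation in `A`.
#'
#' @param annotations an [AnnotationSet-class].
#' @param ontology an [OntologyGraph-class].
#' @param map a [GeneralTaxonMap-class].
#' @return a [CountTable-class].
#' @export
cumulativeTermCounts <- function(annotations, ontology, map) {
  rec <- annotations(annotations)
  nsMap <- setNames(ontology@termNamespace[ontology@terms], ontology@terms)
  if (!nrow(rec)) {
    return(new("CountTable",
               ctg = data.frame(taxon = character(), go_id = character(),
                                c_tg = integer()),
               cg = setNames(integer(), character()),
               cAt = data.frame(namespace = character(), taxon = character(),
                                c_At = integer()),
               cA = setNames(integer(), character()), nsMap = nsMap))
  }
  gen <- toGeneral(map, rec$taxon)
  anc <- .ancestorList(ontology, unique(rec$go_id))
  nAnc <- lengths(anc)[rec$go_id]
  ## expand each record to (protein, taxon, ancestor term)
  dt <- data.table(
    protein = rep(rec$protein, nAnc),
    taxon = rep(gen, nAnc),
    go_id = unlist(anc[rec$go_id], use.names = FALSE))
  dt <- unique(dt)
  ctg <- dt[, .(c_tg = uniqueN(protein)), by = .(taxon, go_id)]
  cgdt <- dt[, .(c_g = uniqueN(protein)), by = go_id]
  cg <- setNames(as.integer(cgdt$c_g), cgdt$go_id)
  ## sub-ontology membership from the direct annotations
  direct <- data.table(protein = rec$protein, taxon = gen,
                       namespace = unname(nsMap[rec$go_id]))
  cAtdt <- direct[, .(c_At = uniqueN(protein)), by = .(namespace, taxon)]
  cAdt <- direct[, .(c_A = uniqueN(protein)), by = namespace]
  cA <- setNames(as.integer(cAdt$c_A), cAdt$namespace)
  new("CountTable",
      ctg = as.data.frame(ctg[, .(taxon, go_id, c_tg = as.integer(c_tg))]),
      cg = cg,
      cAt = as.data.frame(cAtdt[, .(namespace, taxon, c_At = as.integer(c_At))]),
      cA = cA, nsMap = nsMap)
}

#' Select frequent GO terms
#'
#' Terms whose cumulative absolute frequency `c_g` reaches the cutoff
#' (default 500). Rarer terms are not scored directly; propagation later
#' recovers many of them.
#'
#' @param counts a [CountTable-class].
#' @param cutoff minimum `c_g`; terms with `c_g >= cutoff` are kept (the
#'   exclusion rule is "lower than the cutoff", so the boundary is kept).
#' @return character vector of term ids.
#' @export
selectFrequentTerms <- function(counts, cutoff = 500) {
  stopifnot(cutoff >= 0)
  names(counts@cg)[counts@cg >= cutoff]
}

## scalar/vector count lookups
.lookupCtg <- function(counts, t, g) {
  x <- counts@ctg
  idx <- match(paste(t, g), paste(x$taxon, x$go_id))
  out <- x$c_tg[idx]
  out[is.na(out)] <- 0L
  out
}

.lookupCAt <- function(counts, ns, t) {
  x <- counts@cAt
  idx <- match(paste(ns, t), paste(x$namespace, x$taxon))
  out <- x$c_At[idx]
  out[is.na(out)] <- 0L
  out
}

#' Relative probability of a term-taxon association
#'
#' The within-taxon cumulative frequency of the term normalised by its
#' global frequency:
#' `P_rel(t, g) = (c_tg / c_At) / (c_g / c_A)`,
#' where the sub-ontology `A` is the term's namespace. `P_rel = 1` means the
#' taxon uses the term exactly as often as the annotation corpus at large;
#' values above/below 1 indicate enrichment/depletion.
#'
#' @param counts a [CountTable-class].
#' @param t general taxon id(s).
#' @param g term id(s) (recycled against `t`).
#' @return numeric vector of relative probabilities; `NaN` when a
#'   denominator (`c_At` or `c_g`) is zero, which callers route to the
#'   zero-count policy.
#' @export
relativeProbability <- function(counts, t, g) {
  n <- max(length(t), length(g))
  t <- rep_len(as.character(t), n)
  g <- rep_len(as.character(g), n)
  ns <- unname(counts@nsMap[g])
  ctg <- .lookupCtg(counts, t, g)
  cAt <- .lookupCAt(counts, ns, t)
  cg <- unname(counts@cg[g])
  cg[is.na(cg)] <- 0L
  cA <- unname(counts@cA[ns])
  out <- (ctg / cAt) / (cg / cA)
  out[cAt == 0 | is.na(cg) | cg == 0] <- NaN
  out
}
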
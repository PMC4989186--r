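#' @include AllClasses.R utils.R propagation.R
NULL

#' Expand a constraint set to the dense (general taxa x terms) space
#'
#' Renders every (general taxon, non-obsolete term) cell explicitly:
#' * `in` applies to the taxon's whole reduced subtree and ascends to all
#'   GO ancestors,
#' * `never_in` applies to the subtree and descends to all GO descendants,
#' * cells claimed by both closures (possible only on a set that is not
#'   closed) and explicitly dubious cells render as `dubious`,
#' * everything else is `neutral`.
#'
#' @param set a [ConstraintSet-class].
#' @param tree reduced tree data.frame from [reducedTree()].
#' @param ontology an [OntologyGraph-class].
#' @return character matrix, rows = general taxa, cols = terms.
#' @export
expandFull <- function(set, tree, ontology) {
  taxaIds <- tree$taxon
  terms <- goTerms(ontology)
  terms <- terms[!ontology@obsolete[terms]]
  pos <- matrix(FALSE, length(taxaIds), length(terms),
                dimnames = list(taxaIds, terms))
  neg <- pos
  dub <- pos
  kids <- split(tree$taxon, factor(tree$parent, levels = tree$taxon))
  subtree <- function(t) {
    out <- t; cur <- kids[[t]]
    while (length(cur)) { out <- c(out, cur); cur <- unlist(kids[cur], use.names = FALSE) }
    out
  }
  r <- constraints(set)
  r <- r[r$taxon_id %in% taxaIds & r$go_id %in% terms, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    tset <- subtree(r$taxon_id[i])
    if (r$state[i] == "in") {
      pos[tset, termAncestors(ontology, r$go_id[i])] <- TRUE
    } else if (r$state[i] == "never_in") {
      neg[tset, termDescendants(ontology, r$go_id[i])] <- TRUE
    } else if (r$state[i] == "dubious") {
      dub[r$taxon_id[i], r$go_id[i]] <- TRUE
    }
  }
  state <- matrix("neutral", length(taxaIds), length(terms),
                  dimnames = list(taxaIds, terms))
  state[dub] <- "dubious"
  state[pos & !neg] <- "in"
  state[neg & !pos] <- "never_in"
  state[pos & neg] <- "dubious"
  state
}

#' Re-sparsify a dense constraint map
#'
#' Inverse of [expandFull()] up to closure: non-neutral cells become
#' records (`source = "taxon_propagation"` is not reconstructed; cells are
#' tagged `manual`).
#'
#' @param dense character matrix from [expandFull()].
#' @return a [ConstraintSet-class].
#' @export
sparsifyDense <- function(dense) {
  idx <- which(dense != "neutral", arr.ind = TRUE)
  constraintSet(data.frame(
    go_id = colnames(dense)[idx[, 2]],
    taxon_id = rownames(dense)[idx[, 1]],
    state = dense[idx],
    source = "manual", stringsAsFactors = FALSE))
}

#' Agreement statistics between two dense constraint maps
#'
#' Cell-by-cell comparison over a shared (general taxa x terms) index
#' space. `dubious` counts as neutral: discordance concerns opposite polar
#' claims only. Fractions are reported over two denominators — the dense
#' space (`frac_*`) and the union of cells that are non-neutral in at least
#' one set (`union_frac_*`).
#'
#' @param a,b character matrices from [expandFull()] with identical
#'   dimnames.
#' @return list with counts (`n_total`, `n_both`, `n_only_a`, `n_only_b`,
#'   `n_discordant`, `n_neither`) and the corresponding fractions.
#' @export
compareSets <- function(a, b) {
  if (!identical(dimnames(a), dimnames(b)))
    stop("integrity error: dense maps must share the same index space")
  az <- ifelse(a == "dubious", "neutral", a)
  bz <- ifelse(b == "dubious", "neutral", b)
  aN <- az == "neutral"; bN <- bz == "neutral"
  both <- !aN & !bN & az == bz
  disc <- !aN & !bN & az != bz
  onlyA <- !aN & bN
  onlyB <- aN & !bN
  neither <- aN & bN
  n <- length(az)
  nu <- sum(!neither)
  counts <- c(n_total = n, n_both = sum(both), n_only_a = sum(onlyA),
              n_only_b = sum(onlyB), n_discordant = sum(disc),
              n_neither = sum(neither))
  fr <- function(x, d) if (d > 0) x / d else 0
  list(
    n_total = n,
    n_both = counts[["n_both"]], n_only_a = counts[["n_only_a"]],
    n_only_b = counts[["n_only_b"]], n_discordant = counts[["n_discordant"]],
    n_neither = counts[["n_neither"]],
    frac_both = fr(counts[["n_both"]], n),
    frac_only_a = fr(counts[["n_only_a"]], n),
    frac_only_b = fr(counts[["n_only_b"]], n),
    frac_discordant = fr(counts[["n_discordant"]], n),
    frac_neither = fr(counts[["n_neither"]], n),
    union_frac_both = fr(counts[["n_both"]], nu),
    union_frac_only_a = fr(counts[["n_only_a"]], nu),
    union_frac_only_b = fr(counts[["n_only_b"]], nu),
    union_frac_discordant = fr(counts[["n_discordant"]], nu))
}

#' Per-namespace coverage of a constraint set
#'
#' For each sub-ontology, the number and fraction of non-obsolete terms that
#' carry at least one polar (`in` or `never_in`) constraint for at least one
#' general taxon. Dubious cells are not counted: dubious means no decision
#' was made.
#'
#' @param set a [ConstraintSet-class].
#' @param ontology an [OntologyGraph-class].
#' @return data.frame (`namespace`, `n_terms`, `n_constrained`, `fraction`).
#' @export
coverageStats <- function(set, ontology) {
  terms <- goTerms(ontology)
  terms <- terms[!ontology@obsolete[terms]]
  ns <- ontology@termNamespace[terms]
  r <- constraints(set)
  touched <- unique(r$go_id[r$state %in% c("in", "never_in")])
  touched <- intersect(touched, terms)
  nsLevels <- c("biological_process", "molecular_function", "cellular_component")
  out <- data.frame(
    namespace = nsLevels,
    n_terms = vapply(nsLevels, function(x) sum(ns == x), integer(1)),
    n_constrained = vapply(nsLevels, function(x)
      sum(ontology@termNamespace[touched] == x), integer(1)),
    stringsAsFactors = FALSE)
  out$fraction <- ifelse(out$n_terms > 0, out$n_constrained / out$n_terms, 0)
  rownames(out) <- NULL
  out
}
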
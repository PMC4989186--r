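#' @include AllClasses.R utils.R reduction.R constraints-io.R
NULL

## Internal state coding for propagation:
##   0 = neutral, 1 = positive, -1 = negative, 2 = ambiguous.
.ST_NEUTRAL <- 0L; .ST_POS <- 1L; .ST_NEG <- -1L; .ST_AMB <- 2L

.stateToConstraint <- c("neutral", "in", "never_in", "dubious")
.codeToState <- function(code) .stateToConstraint[match(code, c(0L, 1L, -1L, 2L))]
.stateToCode <- function(state) c(0L, 1L, -1L, 2L)[match(state, .stateToConstraint)]
.labelToCode <- function(label) {
  c(positive = 1L, negative = -1L, neutral = 0L)[label]
}

## ---- tree machinery -----------------------------------------------------

## Precompute index structures for a reduced tree (data.frame taxon/parent).
.treeIndex <- function(tree) {
  n <- nrow(tree)
  parent <- match(tree$parent, tree$taxon)          # NA at root
  if (sum(is.na(parent)) != 1L)
    stop("integrity error: reduced tree must have exactly one root")
  kids <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  depth <- .taxDepths(data.frame(taxon = tree$taxon, parent = tree$parent))
  if (anyNA(depth)) stop("integrity error: reduced tree contains a cycle")
  ord <- order(depth[tree$taxon])                    # parents before children
  list(n = n, taxon = tree$taxon, parent = parent,
       children = kids, topDown = ord, bottomUp = rev(ord))
}

## The four rules are interpreted as local *recomputations* over two
## information channels, which makes the fixed point independent of the
## application schedule:
##   down[v] — polarity supported by v's own subtree (seeds included):
##     Rule I  (concordant polar children polarise the parent) and
##     Rule III's conflict detection (opposite or ambiguous children make
##     the parent ambiguous) act on this channel only;
##   final[v] — the exported state: down[v] when non-neutral, otherwise
##     inherited from the parent's final state:
##     Rule II  (a polar parent polarises neutral children),
##     Rule IV  (a child whose subtree opposes the polar parent blocks
##               inheritance; the neutral children become ambiguous),
##     and the descent of ambiguity (Rule III's "neutral siblings become
##     ambiguous", generalised: an ambiguous parent leaves its neutral
##     children undecided-ambiguous).
## Child-driven rules never read context-derived states, so information
## cannot echo back up the tree; both channels are monotone closures and
## any exhaustive application order reaches the same fixed point.

## Rule I + III: recompute the subtree channel of node p.
.downAt <- function(p, down, frozen, seedState, idx) {
  if (frozen[p]) return(seedState[p])
  ch <- idx$children[[p]]
  if (is.null(ch) || !length(ch)) return(down[p])
  cs <- down[ch]
  if (any(cs == .ST_AMB) || (any(cs == .ST_POS) && any(cs == .ST_NEG)))
    return(.ST_AMB)
  if (any(cs == .ST_POS)) return(.ST_POS)
  if (any(cs == .ST_NEG)) return(.ST_NEG)
  down[p]
}

## Rule II + IV + ambiguity descent: recompute the exported state of v.
.finalAt <- function(v, down, final, frozen, idx) {
  if (down[v] != .ST_NEUTRAL) return(down[v])
  p <- idx$parent[v]
  if (is.na(p)) return(.ST_NEUTRAL)
  pf <- final[p]
  if (pf == .ST_NEUTRAL) return(.ST_NEUTRAL)
  if (pf == .ST_AMB) return(.ST_AMB)
  sibs <- idx$children[[p]]
  if (any(down[sibs] == -pf)) return(.ST_AMB)    # Rule IV
  pf                                             # Rule II
}

## Deterministic reference schedule: one bottom-up sweep of the
## child-driven rules, one top-down sweep of the parent-driven rules,
## repeated until stable (a single double-sweep suffices; the loop is a
## safety net).
.sweepFixpoint <- function(seedState, frozen, idx) {
  seedState <- as.integer(seedState)
  down <- ifelse(frozen, seedState, .ST_NEUTRAL)
  final <- rep(.ST_NEUTRAL, idx$n)
  repeat {
    changed <- FALSE
    for (p in idx$bottomUp) {
      new <- .downAt(p, down, frozen, seedState, idx)
      if (new != down[p]) { down[p] <- new; changed <- TRUE }
    }
    for (v in idx$topDown) {
      new <- .finalAt(v, down, final, frozen, idx)
      if (new != final[v]) { final[v] <- new; changed <- TRUE }
    }
    if (!changed) return(final)
  }
}

## Chaotic iteration: the same rule recomputations applied node-by-node in
## a random order until quiescent. Independent schedule for confluence
## checks.
.chaoticFixpoint <- function(seedState, frozen, idx) {
  seedState <- as.integer(seedState)
  down <- ifelse(frozen, seedState, .ST_NEUTRAL)
  final <- rep(.ST_NEUTRAL, idx$n)
  tasks <- rbind(cbind(seq_len(idx$n), 1L), cbind(seq_len(idx$n), 2L))
  repeat {
    changed <- FALSE
    for (i in sample.int(nrow(tasks))) {
      v <- tasks[i, 1L]
      if (tasks[i, 2L] == 1L) {
        new <- .downAt(v, down, frozen, seedState, idx)
        if (new != down[v]) { down[v] <- new; changed <- TRUE }
      } else {
        new <- .finalAt(v, down, final, frozen, idx)
        if (new != final[v]) { final[v] <- new; changed <- TRUE }
      }
    }
    if (!changed) return(final)
  }
}

## ---- taxonomy propagation ----------------------------------------------

#' Propagate seed polarities over the reduced taxonomic tree
#'
#' Extends the per-term polarities of the robust general taxa to the rest of
#' the reduced tree by iterating four local rules to a fixed point:
#' * Rule I — concordant polar children polarise their neutral parent;
#' * Rule II — a polar parent polarises its neutral children;
#' * Rule III — siblings of opposite polarity (or an ambiguous sibling)
#'   make the neutral parent and the neutral siblings ambiguous;
#' * Rule IV — a polar parent with a child of the opposite polarity makes
#'   its remaining neutral children ambiguous.
#'
#' Seed polarities are frozen and never change; `ambiguous` is absorbing.
#' The deterministic schedule is a bottom-up sweep of the child-driven rules
#' followed by a top-down sweep of the parent-driven rules, repeated until
#' stable; [chaoticTaxonomyFixpoint()] provides an order-randomised
#' reference for confluence checks.
#'
#' @param seeds polarity table from [assignPolarity()] (columns `taxon`,
#'   `go_id`, `label`, and optionally `n_proteins`, `p_value`); polar labels
#'   are frozen, neutral seeds are left open to propagation.
#' @param tree reduced tree data.frame from [reducedTree()].
#' @return data.frame (`go_id`, `taxon`, `state` in the internal
#'   -1/0/1/2 coding, `frozen`, `source`) covering every tree node for every
#'   seeded term.
#' @export
propagateTaxonomy <- function(seeds, tree) {
  idx <- .treeIndex(tree)
  terms <- unique(seeds$go_id)
  seedCode <- .labelToCode(seeds$label)
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    g <- terms[i]
    sel <- seeds$go_id == g
    state <- rep(.ST_NEUTRAL, idx$n)
    ti <- match(seeds$taxon[sel], idx$taxon)
    state[ti] <- seedCode[sel]
    frozen <- rep(FALSE, idx$n)
    frozen[ti[state[ti] != .ST_NEUTRAL]] <- TRUE
    res <- .sweepFixpoint(state, frozen, idx)
    src <- ifelse(frozen, "frequency", "taxon_propagation")
    out[[i]] <- data.frame(go_id = g, taxon = idx$taxon, state = res,
                           frozen = frozen, source = src,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname propagateTaxonomy
#' @param seedState integer vector over `tree` rows (-1/0/1/2 coding) of
#'   seed polarities (non-zero entries should be frozen).
#' @param frozen logical vector over `tree` rows.
#' @export
chaoticTaxonomyFixpoint <- function(seedState, frozen, tree) {
  .chaoticFixpoint(seedState, frozen, .treeIndex(tree))
}

#' @rdname propagateTaxonomy
#' @export
sweepTaxonomyFixpoint <- function(seedState, frozen, tree) {
  .sweepFixpoint(seedState, frozen, .treeIndex(tree))
}

## ---- GO propagation (true path rule) -----------------------------------

#' Propagate constraint states over the GO graph
#'
#' True-path closure, applied per taxon after taxonomy propagation:
#' positive ("in") states ascend to every `is_a`/`part_of` ancestor,
#' negative ("never in") states descend to every descendant. A term reached
#' by both closures in the same taxon becomes ambiguous. Frozen seed states
#' never change; existing ambiguous states are absorbing. Entries created or
#' repolarised here are tagged `source = "go_propagation"`.
#'
#' @param states data.frame as returned by [propagateTaxonomy()].
#' @param ontology an [OntologyGraph-class].
#' @return data.frame of the same shape, closed under the true path rule
#'   (rows may be added for newly reached terms).
#' @export
propagateGO <- function(states, ontology) {
  out <- vector("list", 0L)
  for (t in unique(states$taxon)) {
    sub <- states[states$taxon == t, , drop = FALSE]
    st <- setNames(sub$state, sub$go_id)
    frozen <- setNames(sub$frozen, sub$go_id)
    src <- setNames(sub$source, sub$go_id)
    pos0 <- names(st)[st == .ST_POS]
    neg0 <- names(st)[st == .ST_NEG]
    pa <- termAncestors(ontology, pos0, includeSelf = TRUE)
    nd <- termDescendants(ontology, neg0, includeSelf = TRUE)
    allTerms <- union(names(st), union(pa, nd))
    newTerms <- setdiff(allTerms, names(st))
    if (length(newTerms)) {
      st[newTerms] <- .ST_NEUTRAL
      frozen[newTerms] <- FALSE
      src[newTerms] <- "go_propagation"
    }
    inPa <- allTerms %in% pa
    inNd <- allTerms %in% nd
    cur <- st[allTerms]
    new <- cur
    open <- !frozen[allTerms] & cur != .ST_AMB
    new[open & inPa & inNd] <- .ST_AMB
    new[open & inPa & !inNd] <- .ST_POS
    new[open & !inPa & inNd] <- .ST_NEG
    changedOrNew <- (new != cur) | (allTerms %in% newTerms)
    src[allTerms][changedOrNew] <- "go_propagation"
    ## obsolete terms never receive constraints
    keepAlive <- !isObsolete(ontology, allTerms)
    keepAlive[is.na(keepAlive)] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      go_id = allTerms[keepAlive], taxon = t,
      state = unname(new[keepAlive]),
      frozen = unname(frozen[allTerms][keepAlive]),
      source = unname(src[allTerms][keepAlive]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- assembly -----------------------------------------------------------

#' Assemble a ConstraintSet from propagated states
#'
#' Drops neutral cells (neutral is implied by absence) and converts the
#' internal coding to the exported states `in` / `never_in` / `dubious`.
#' Seed support counts and p-values are attached where available.
#'
#' @param states data.frame from [propagateTaxonomy()] / [propagateGO()].
#' @param seeds optional polarity table carrying `n_proteins` / `p_value`.
#' @return a [ConstraintSet-class].
#' @export
constraintsFromStates <- function(states, seeds = NULL) {
  keep <- states$state != .ST_NEUTRAL
  r <- states[keep, , drop = FALSE]
  rec <- data.frame(go_id = r$go_id, taxon_id = r$taxon,
                    state = .codeToState(r$state),
                    source = r$source,
                    n_proteins = 0L, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(seeds) && nrow(rec)) {
    m <- match(paste(rec$go_id, rec$taxon_id),
               paste(seeds$go_id, seeds$taxon))
    hit <- !is.na(m)
    if (!is.null(seeds$n_proteins))
      rec$n_proteins[hit] <- as.integer(seeds$n_proteins[m[hit]])
    if (!is.null(seeds$p_value))
      rec$p_value[hit] <- seeds$p_value[m[hit]]
  }
  constraintSet(rec)
}

## states back from a ConstraintSet (for re-closure after combination)
.statesFromConstraints <- function(set) {
  r <- constraints(set)
  data.frame(go_id = r$go_id, taxon = r$taxon_id,
             state = .stateToCode(r$state),
             frozen = FALSE, source = r$source, stringsAsFactors = FALSE)
}

#' Translate only_in / never_in triples into a ConstraintSet
#'
#' `only_in(g, t)` means the term may annotate only `t` and its descendants:
#' it becomes `in(t, g)` plus `never_in(t', g)` for every general taxon `t'`
#' disjoint from `t` (neither an ancestor nor a descendant in the reduced
#' tree). `never_in` triples pass through unchanged. Everything is tagged
#' `source = "manual"`.
#'
#' @param triples data.frame from [parseGOCConstraints()].
#' @param tree reduced tree data.frame from [reducedTree()].
#' @param map a [GeneralTaxonMap-class] used to resolve triple taxa onto
#'   general taxa.
#' @return a [ConstraintSet-class].
#' @export
translateOnlyIn <- function(triples, tree, map) {
  gen <- toGeneral(map, triples$taxon_id)
  if (anyNA(gen))
    stop("integrity error: unknown taxon in constraint triples: ",
         paste(head(triples$taxon_id[is.na(gen)], 5), collapse = ", "))
  ## ancestor chains within the reduced tree
  parent <- setNames(tree$parent, tree$taxon)
  anc <- function(t) {
    out <- t
    while (!is.na(parent[[t]])) { t <- parent[[t]]; out <- c(out, t) }
    out
  }
  kids <- split(tree$taxon, factor(tree$parent, levels = tree$taxon))
  desc <- function(t) {
    out <- t; cur <- kids[[t]]
    while (length(cur)) { out <- c(out, cur); cur <- unlist(kids[cur], use.names = FALSE) }
    out
  }
  rows <- list()
  for (i in seq_len(nrow(triples))) {
    t <- gen[i]; g <- triples$go_id[i]
    if (triples$relation[i] == "never_in") {
      rows[[length(rows) + 1L]] <- data.frame(go_id = g, taxon_id = t,
                                              state = "never_in",
                                              stringsAsFactors = FALSE)
    } else {
      disjoint <- setdiff(tree$taxon, union(anc(t), desc(t)))
      rows[[length(rows) + 1L]] <- data.frame(
        go_id = g, taxon_id = c(t, disjoint),
        state = c("in", rep("never_in", length(disjoint))),
        stringsAsFactors = FALSE)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(go_id = character(), taxon_id = character(),
               state = character(), stringsAsFactors = FALSE)
  rec <- unique(rec)
  rec$source <- "manual"
  constraintSet(rec)
}

#' Combine two constraint sets with priority
#'
#' Union of the two sets; where both assert a non-neutral state for the same
#' (taxon, term) pair and the states differ, the primary set wins and the
#' conflict is recorded. The combined set is then re-closed over the GO
#' graph with [propagateGO()].
#'
#' @param primary,secondary [ConstraintSet-class] objects over the same
#'   reduced tree and ontology.
#' @param ontology an [OntologyGraph-class] for the re-closure.
#' @return a [ConstraintSet-class]; conflicts are attached as a data.frame
#'   in `attr(, "conflicts")`.
#' @export
combineSets <- function(primary, secondary, ontology) {
  p <- constraints(primary)
  s <- constraints(secondary)
  keyP <- paste(p$go_id, p$taxon_id)
  keyS <- paste(s$go_id, s$taxon_id)
  overlap <- keyS %in% keyP
  conflict <- s[overlap & s$state != p$state[match(keyS, keyP)], , drop = FALSE]
  merged <- rbind(p, s[!overlap, , drop = FALSE])
  states <- .statesFromConstraints(constraintSet(merged))
  ## freeze explicit records so the re-closure cannot overwrite the
  ## prioritised decisions
  states$frozen <- TRUE
  closed <- propagateGO(states, ontology)
  out <- constraintsFromStates(closed)
  rec <- constraints(out)
  m <- match(paste(rec$go_id, rec$taxon_id), paste(merged$go_id, merged$taxon_id))
  hit <- !is.na(m)
  rec$source[hit] <- merged$source[m[hit]]
  rec$n_proteins[hit] <- merged$n_proteins[m[hit]]
  rec$p_value[hit] <- merged$p_value[m[hit]]
  out <- constraintSet(rec)
  attr(out, "conflicts") <- conflict
  out
}

#' Resolve the constraint state for any (taxon, term)
#'
#' Looks a pair up through the general-taxon reduction: the state recorded
#' for `toGeneral(taxon)` and the canonical term id, `"neutral"` when no
#' record exists.
#'
#' @param set a [ConstraintSet-class].
#' @param map a [GeneralTaxonMap-class].
#' @param taxon taxon id(s).
#' @param go term id(s), recycled against `taxon`.
#' @param ontology optional [OntologyGraph-class] for alt-id resolution.
#' @return character vector of states.
#' @export
lookupConstraint <- function(set, map, taxon, go, ontology = NULL) {
  n <- max(length(taxon), length(go))
  taxon <- rep_len(as.character(taxon), n)
  go <- rep_len(as.character(go), n)
  if (!is.null(ontology)) {
    res <- resolveTermIds(ontology, go)
    go[!is.na(res)] <- res[!is.na(res)]
  }
  gen <- toGeneral(map, taxon)
  r <- constraints(set)
  m <- match(paste(go, gen), paste(r$go_id, r$taxon_id))
  out <- r$state[m]
  out[is.na(out)] <- "neutral"
  out
}
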
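#' @include AllClasses.R reduction.R counts.R inference.R propagation.R
NULL

#' Build a group spec from a taxonomy rank
#'
#' One group per node of the given rank (default `superkingdom`), with no
#' named reference — intended for [selectRobustTaxa()] with
#' `autoReference = TRUE`. Useful for synthetic taxonomies where the shipped
#' kingdom table does not apply.
#'
#' @param taxonomy a [TaxonomyTree-class].
#' @param rank rank of the group subsumers.
#' @return a group spec data.frame, see [groupSpec()].
#' @export
groupSpecFromRanks <- function(taxonomy, rank = "superkingdom") {
  nd <- taxonomy@nodes
  sub <- nd$taxon[nd$rank == rank]
  if (!length(sub))
    stop("no taxa of rank '", rank, "' in the taxonomy")
  groupSpec(subsumer = sub, name = nd$name[match(sub, nd$taxon)])
}

#' Infer taxon constraints from annotations
#'
#' The full inference pipeline:
#' 1. reduce the taxonomy to general taxa ([buildGeneralTaxonMap()]),
#' 2. partition them into groups and select the robust general taxa
#'    ([partitionGroups()], [selectRobustTaxa()]),
#' 3. count cumulative term frequencies and keep frequent terms
#'    ([cumulativeTermCounts()], [selectFrequentTerms()]),
#' 4. assign seed polarities with the closed/open-world rule and the
#'    experimental override ([assignPolarity()]),
#' 5. optionally attach bootstrap p-values ([bootstrapPvalues()]),
#' 6. propagate over the reduced tree (Rules I-IV) and the GO graph
#'    (true path rule) ([propagateTaxonomy()], [propagateGO()]).
#'
#' @param ontology an [OntologyGraph-class].
#' @param taxonomy a [TaxonomyTree-class].
#' @param annotations an [AnnotationSet-class].
#' @param groups group spec data.frame; `NULL` selects the shipped
#'   kingdom-level default.
#' @param rankOverrides optional rank-override table, see
#'   [buildGeneralTaxonMap()].
#' @param cutoff cumulative-frequency cutoff for scored terms.
#' @param robustThreshold unique-annotation ratio for robustness.
#' @param autoReference pick group references by maximum unique-term count.
#' @param thetaNeg,thetaPos polarity label thresholds.
#' @param experimentalCodes evidence codes treated as experimental.
#' @param bootstrapReps bootstrap replicates for seed p-values (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @param details return intermediate objects as well.
#' @return a [ConstraintSet-class]; with `details = TRUE`, a list with
#'   elements `constraints`, `map`, `tree`, `robust`, `counts`, `frequent`,
#'   `seeds`, `states`.
#' @export
inferConstraints <- function(ontology, taxonomy, annotations,
                             groups = NULL, rankOverrides = NULL,
                             cutoff = 500, robustThreshold = 0.75,
                             autoReference = FALSE,
                             thetaNeg = -0.6, thetaPos = 0.2,
                             experimentalCodes = .EXPERIMENTAL_CODES,
                             bootstrapReps = 0, seed = 1,
                             details = FALSE) {
  if (is.null(groups)) groups <- defaultGroupSpec()
  map <- buildGeneralTaxonMap(taxonomy, rankOverrides)
  tree <- reducedTree(taxonomy, map)
  assignment <- partitionGroups(taxonomy, groups, map)
  robust <- selectRobustTaxa(annotations, map, assignment, groups,
                             threshold = robustThreshold,
                             autoReference = autoReference)
  counts <- cumulativeTermCounts(annotations, ontology, map)
  frequent <- selectFrequentTerms(counts, cutoff)
  expPairs <- experimentalPairs(annotations, ontology, map,
                                codes = experimentalCodes)
  seeds <- assignPolarity(counts, frequent, robust$robust,
                          experimental = expPairs,
                          thetaNeg = thetaNeg, thetaPos = thetaPos)
  if (bootstrapReps > 0)
    seeds <- bootstrapPvalues(annotations, seeds, counts, ontology, map,
                              nReps = bootstrapReps, seed = seed,
                              thetaNeg = thetaNeg, thetaPos = thetaPos,
                              codes = experimentalCodes)
  states <- propagateTaxonomy(seeds, tree)
  states <- propagateGO(states, ontology)
  set <- constraintsFromStates(states, seeds)
  if (!details) return(set)
  list(constraints = set, map = map, tree = tree, robust = robust,
       counts = counts, frequent = frequent, seeds = seeds, states = states)
}

#' Export a per-term coloured reduced tree as DOT
#'
#' Graphviz rendering of the constraint states of one GO term over the
#' reduced tree: green = in, red = never_in, yellow = dubious,
#' lightblue = neutral.
#'
#' @param set a [ConstraintSet-class].
#' @param tree reduced tree data.frame from [reducedTree()].
#' @param go a term id.
#' @param taxonomy optional [TaxonomyTree-class] for node labels.
#' @param file optional output path.
#' @return DOT lines, invisibly.
#' @export
exportTreeDot <- function(set, tree, go, taxonomy = NULL, file = NULL) {
  r <- constraints(set)
  r <- r[r$go_id == go, , drop = FALSE]
  st <- setNames(r$state, r$taxon_id)
  col <- c("in" = "green", never_in = "red", dubious = "yellow",
           neutral = "lightblue")
  lines <- c("digraph reduced_tree {", "  node [style=filled];")
  for (t in tree$taxon) {
    s <- if (t %in% names(st)) st[[t]] else "neutral"
    lab <- if (!is.null(taxonomy)) taxName(taxonomy, t) else t
    lines <- c(lines, sprintf('  "%s" [label="%s", fillcolor=%s];',
                              t, lab, col[[s]]))
  }
  e <- tree[!is.na(tree$parent), , drop = FALSE]
  lines <- c(lines,
             sprintf('  "%s" -> "%s";', e$parent, e$taxon),
             "}")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
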
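#' @include AllClasses.R utils.R
NULL

## NCBI rank ladder above (and including) "class"; "domain" covers the
## newer taxdump spelling of superkingdom. "no rank" nodes are transparent
## when walking towards the general taxon.
.GENERAL_RANKS <- c("domain", "superkingdom", "kingdom", "subkingdom",
                    "superphylum", "phylum", "subphylum", "superclass",
                    "class")

#' Collapse a taxonomy to general taxa
#'
#' A *general taxon* is a node ranked "class" or above in the NCBI ladder.
#' Every taxon is mapped to its most specific ancestor-or-self that is a
#' general taxon; nodes ranked `"no rank"` are transparent during the walk;
#' taxa with no class-or-above ancestor map to the root. The root itself is
#' always a general taxon (the catch-all).
#'
#' Rank overrides (a two-column data.frame `taxon_id`, `rank`, or a TSV path
#' of the same shape) are applied before the walk; they replace external
#' rank-consensus lookups for nodes whose NCBI rank is missing.
#'
#' @param taxonomy a [TaxonomyTree-class].
#' @param rankOverrides optional data.frame (`taxon_id`, `rank`) or TSV path.
#' @return a [GeneralTaxonMap-class].
#' @export
buildGeneralTaxonMap <- function(taxonomy, rankOverrides = NULL) {
  nd <- taxonomy@nodes
  rank <- setNames(nd$rank, nd$taxon)
  if (!is.null(rankOverrides)) {
    if (is.character(rankOverrides))
      rankOverrides <- read.delim(rankOverrides, colClasses = "character")
    ov <- as.character(rankOverrides[[1]])
    unknown <- setdiff(ov, nd$taxon)
    if (length(unknown))
      stop("rank override for unknown taxon: ",
           paste(head(unknown, 5), collapse = ", "))
    rank[ov] <- as.character(rankOverrides[[2]])
  }
  parent <- setNames(nd$parent, nd$taxon)
  root <- taxRoot(taxonomy)
  isGeneral <- rank %in% .GENERAL_RANKS
  names(isGeneral) <- nd$taxon
  isGeneral[root] <- TRUE

  ## memoised upward walk
  mapping <- setNames(rep(NA_character_, nrow(nd)), nd$taxon)
  mapping[names(isGeneral)[isGeneral]] <- names(isGeneral)[isGeneral]
  for (tx in nd$taxon) {
    if (!is.na(mapping[tx])) next
    chain <- character()
    cur <- tx
    while (is.na(mapping[cur])) {
      chain <- c(chain, cur)
      cur <- parent[[cur]]
    }
    mapping[chain] <- mapping[[cur]]
  }
  new("GeneralTaxonMap",
      generalTaxa = names(isGeneral)[isGeneral],
      mapping = mapping)
}

#' Map taxa to their general taxon
#'
#' @param map a [GeneralTaxonMap-class].
#' @param ids taxon ids (character or coercible).
#' @return character vector of general taxon ids (`NA` for unknown taxa).
#' @export
toGeneral <- function(map, ids) {
  unname(map@mapping[as.character(ids)])
}

#' Parent relation among general taxa
#'
#' Projects the full taxonomy onto the general taxa: the reduced parent of a
#' general taxon is the general taxon of its nearest general ancestor.
#'
#' @param taxonomy a [TaxonomyTree-class].
#' @param map a [GeneralTaxonMap-class].
#' @return data.frame (`taxon`, `parent`) over general taxa, `NA` parent at
#'   the root.
#' @export
reducedTree <- function(taxonomy, map) {
  g <- generalTaxa(map)
  fullParent <- taxParent(taxonomy, g)
  redParent <- ifelse(is.na(fullParent), NA_character_, toGeneral(map, fullParent))
  data.frame(taxon = g, parent = redParent, stringsAsFactors = FALSE)
}

#' Group specification for the taxonomy partition
#'
#' Builds the kingdom-level grouping used to pick reference taxa for
#' robustness. Each group is a subsumer subtree, optionally minus an excluded
#' subtree (used to split Metazoa into Chordata and the rest), with a
#' reference general taxon and a reference model organism.
#'
#' `defaultGroupSpec()` returns the spec shipped with the package: seven
#' kingdom/superkingdom groups with Metazoa split into "Chordata" and
#' "Metazoa excluding Chordata".
#'
#' @param subsumer,name,exclude,reference,model character vectors of equal
#'   length (`exclude`, `reference`, `model` may contain `NA`).
#' @return data.frame with columns `subsumer`, `name`, `exclude`,
#'   `reference`, `model`.
#' @export
groupSpec <- function(subsumer, name, exclude = NA, reference = NA,
                      model = NA) {
  data.frame(subsumer = as.character(subsumer), name = as.character(name),
             exclude = as.character(exclude),
             reference = as.character(reference),
             model = as.character(model), stringsAsFactors = FALSE)
}

#' @rdname groupSpec
#' @export
defaultGroupSpec <- function() {
  path <- system.file("extdata", "default_groups.tsv",
                      package = "taxonConstraints", mustWork = TRUE)
  sp <- read.delim(path, colClasses = "character")
  sp$exclude[!nzchar(sp$exclude)] <- NA_character_
  sp
}

#' Assign general taxa to groups
#'
#' Every general taxon inside a group subsumer's subtree (minus its excluded
#' subtree) is assigned to that group; general taxa outside all subsumers
#' stay unassigned (`NA`). Overlapping subsumers that are not resolved by an
#' exclusion are a specification error.
#'
#' @param taxonomy a [TaxonomyTree-class].
#' @param spec a group spec data.frame, see [groupSpec()].
#' @param map a [GeneralTaxonMap-class].
#' @return named character vector: general taxon id -> group name (`NA` when
#'   unassigned).
#' @export
partitionGroups <- function(taxonomy, spec, map) {
  g <- generalTaxa(map)
  assignment <- setNames(rep(NA_character_, length(g)), g)
  for (i in seq_len(nrow(spec))) {
    memb <- taxDescendants(taxonomy, spec$subsumer[i])
    if (!is.na(spec$exclude[i]))
      memb <- setdiff(memb, taxDescendants(taxonomy, spec$exclude[i]))
    memb <- intersect(memb, g)
    clash <- memb[!is.na(assignment[memb])]
    if (length(clash))
      stop("group spec error: overlapping subsumers without exclusion; taxa ",
           paste(head(clash, 5), collapse = ", "),
           " fall in both '", assignment[clash[1]], "' and '", spec$name[i], "'")
    assignment[memb] <- spec$name[i]
    if (!is.na(spec$reference[i]) &&
        !(spec$reference[i] %in% memb))
      stop("group spec error: reference general taxon ", spec$reference[i],
           " lies outside group '", spec$name[i], "'")
  }
  assignment
}

#' Count unique GO terms per general taxon
#'
#' The number of distinct GO ids annotated to any protein whose taxon maps
#' to the general taxon. All evidence codes count by default; restrict the
#' [AnnotationSet-class] beforehand to change that.
#'
#' @param annotations an [AnnotationSet-class].
#' @param map a [GeneralTaxonMap-class].
#' @return named integer vector over general taxa (zero where unannotated).
#' @export
uniqueTermCounts <- function(annotations, map) {
  rec <- annotations(annotations)
  gen <- toGeneral(map, rec$taxon)
  counts <- setNames(rep(0L, length(generalTaxa(map))), generalTaxa(map))
  if (nrow(rec)) {
    tab <- tapply(rec$go_id, gen, function(x) length(unique(x)))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Select robust general taxa
#'
#' A general taxon is *robust* — annotated well enough for closed-world
#' inference — when its unique-GO-term count strictly exceeds
#' `threshold` (default 0.75) times the count of its group's reference
#' taxon. References are robust by construction (their ratio is 1);
#' unassigned general taxa are never robust.
#'
#' With `autoReference = TRUE` the reference of each group is the general
#' taxon with the highest number of unique GO terms (ties broken by smaller
#' taxon id), instead of the references named in the spec.
#'
#' @param annotations an [AnnotationSet-class].
#' @param map a [GeneralTaxonMap-class].
#' @param assignment named group assignment from [partitionGroups()].
#' @param spec the group spec (used for its named references).
#' @param threshold ratio in (0, 1].
#' @param autoReference pick references by maximum unique-term count.
#' @return list with `robust` (character vector), `uniqueTerms` (named
#'   integer), `reference` (named character, group -> reference taxon),
#'   `threshold`.
#' @export
selectRobustTaxa <- function(annotations, map, assignment, spec,
                             threshold = 0.75, autoReference = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  counts <- uniqueTermCounts(annotations, map)
  groups <- unique(assignment[!is.na(assignment)])
  reference <- setNames(rep(NA_character_, length(groups)), groups)
  for (grp in groups) {
    members <- names(assignment)[!is.na(assignment) & assignment == grp]
    if (autoReference) {
      cnt <- counts[members]
      best <- members[cnt == max(cnt)]
      ## deterministic tie-break: smallest taxon id (numeric when possible)
      o <- order(suppressWarnings(as.numeric(best)), best)
      reference[grp] <- best[o[1]]
    } else {
      ref <- spec$reference[spec$name == grp]
      reference[grp] <- ref[1]
    }
    if (is.na(reference[grp]) || counts[reference[grp]] == 0L)
      stop("configuration error: group '", grp,
           "' has no usable reference (zero unique terms)")
  }
  refCount <- counts[reference[assignment]]
  robust <- names(assignment)[!is.na(assignment) &
                              counts[names(assignment)] > threshold * refCount]
  robust <- union(robust, unname(reference))
  list(robust = sort(robust), uniqueTerms = counts,
       reference = reference, threshold = threshold)
}
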
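#' @include AllClasses.R utils.R obo.R taxdump.R gaf.R reduction.R
NULL

## namespace split used for generated ontologies
.NS_LEVELS <- c("biological_process", "molecular_function", "cellular_component")

#' Generate a synthetic benchmark world
#'
#' Builds a self-contained universe with known ground truth: a layered
#' three-namespace ontology DAG, a ranked taxonomy down to species with at
#' least two kingdom-level groups, and a feasibility matrix over
#' (general taxa x terms). Infeasibility is planted on whole
#' (taxonomy-subtree x GO-sub-DAG) blocks — clade-specific loss of a
#' functional module — so the ground truth respects true-path consistency
#' by construction. Deterministic given the seed.
#'
#' @param nTerms total number of ontology terms (split ~50/30/20 over
#'   BP/MF/CC; >= 9).
#' @param nTaxa total number of taxa including the root (>= 8).
#' @param depth number of ranked levels below the root (3..8).
#' @param infeasibleFraction target fraction of infeasible
#'   (general taxon, term) cells.
#' @param seed RNG seed.
#' @param partOfFraction fraction of DAG edges typed `part_of`.
#' @return a [SyntheticWorld-class].
#' @export
generateWorld <- function(nTerms = 60, nTaxa = 30, depth = 5,
                          infeasibleFraction = 0.25, seed = 1,
                          partOfFraction = 0.15) {
  stopifnot(nTerms >= 9, nTaxa >= 8, infeasibleFraction >= 0,
            infeasibleFraction < 1)
  if (depth < 3 || depth > 8)
    stop("parameter error: depth must lie in 3..8")
  if (depth > nTaxa)
    stop("parameter error: depth exceeds the number of taxa")
  .withSeed(seed, {
    ontology <- .generateOntology(nTerms, partOfFraction)
    taxonomy <- .generateTaxonomy(nTaxa, depth)
    map <- buildGeneralTaxonMap(taxonomy)
    feas <- .plantInfeasibility(ontology, taxonomy, map, infeasibleFraction)
  })
  new("SyntheticWorld", ontology = ontology, taxonomy = taxonomy,
      map = map, feasibility = feas,
      params = list(nTerms = nTerms, nTaxa = nTaxa, depth = depth,
                    infeasibleFraction = infeasibleFraction, seed = seed,
                    partOfFraction = partOfFraction))
}

.generateOntology <- function(nTerms, partOfFraction) {
  nBP <- max(3L, round(nTerms * 0.5))
  nMF <- max(3L, round(nTerms * 0.3))
  nCC <- max(3L, nTerms - nBP - nMF)
  sizes <- c(biological_process = nBP, molecular_function = nMF,
             cellular_component = nCC)
  ids <- sprintf("GO:%07d", seq_len(sum(sizes)))
  edges <- list()
  terms <- character(); nss <- character()
  off <- 0L
  for (ns in .NS_LEVELS) {
    n <- sizes[[ns]]
    nsIds <- ids[off + seq_len(n)]
    off <- off + n
    ## layered DAG: root in layer 0, then layers of roughly doubling size
    layer <- integer(n); layer[1] <- 0L
    if (n > 1) {
      nLayers <- max(2L, ceiling(log2(n)))
      layer[-1] <- sort(rep_len(seq_len(nLayers), n - 1L))
    }
    for (i in seq_len(n)[-1]) {
      pool <- nsIds[layer == layer[i] - 1L]
      if (!length(pool)) pool <- nsIds[1]
      nPar <- min(length(pool), sample(1:2, 1))
      par <- sample(pool, nPar)
      type <- ifelse(runif(nPar) < partOfFraction, "part_of", "is_a")
      type[1] <- "is_a"                      # keep >= 1 is_a parent
      edges[[length(edges) + 1L]] <- data.frame(
        child = nsIds[i], parent = par, type = type,
        stringsAsFactors = FALSE)
    }
    terms <- c(terms, nsIds)
    nss <- c(nss, rep(ns, n))
  }
  ed <- unique(do.call(rbind, edges))
  new("OntologyGraph",
      terms = terms,
      termName = setNames(paste("synthetic term", terms), terms),
      termNamespace = setNames(nss, terms),
      obsolete = setNames(rep(FALSE, length(terms)), terms),
      edges = ed,
      altMap = setNames(character(), character()),
      graph = .buildTermGraph(terms, ed))
}

.generateTaxonomy <- function(nTaxa, depth) {
  ladder <- c("superkingdom", "kingdom", "phylum", "class", "order",
              "family", "genus", "species")
  ## always keep superkingdom, class and species; fill the rest in order
  keep <- c("superkingdom", "class", "species")
  extra <- setdiff(ladder, keep)
  ranks <- ladder[ladder %in% c(keep, extra[seq_len(depth - 3L)])]
  nLevels <- length(ranks)
  nFree <- nTaxa - 1L
  ## >= 2 superkingdoms, remaining nodes spread down the levels with the
  ## lower levels wider (species-rich tips)
  sizes <- pmax(2L, round(nFree * (seq_len(nLevels) / sum(seq_len(nLevels)))))
  while (sum(sizes) > nFree) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < nFree) sizes[nLevels] <- sizes[nLevels] + 1L
  taxon <- "1"; parent <- NA_character_; rank <- "no rank"
  prevLevel <- "1"
  nextId <- 2L
  for (lv in seq_len(nLevels)) {
    idsLv <- as.character(seq(nextId, length.out = sizes[lv]))
    nextId <- nextId + sizes[lv]
    par <- sample(prevLevel, sizes[lv], replace = TRUE)
    if (lv > 1) {
      ## every node of the previous level keeps at least one child when room
      need <- setdiff(prevLevel, par)
      need <- need[seq_len(min(length(need), sizes[lv]))]
      par[seq_along(need)] <- need
    }
    taxon <- c(taxon, idsLv)
    parent <- c(parent, par)
    rank <- c(rank, rep(ranks[lv], sizes[lv]))
    prevLevel <- idsLv
  }
  new("TaxonomyTree",
      nodes = data.frame(taxon = taxon, parent = parent, rank = rank,
                         name = paste0("syn_", rank, "_", taxon),
                         stringsAsFactors = FALSE))
}

.plantInfeasibility <- function(ontology, taxonomy, map, frac) {
  g <- generalTaxa(map)
  terms <- goTerms(ontology)
  feas <- matrix(TRUE, length(g), length(terms), dimnames = list(g, terms))
  if (frac <= 0) return(feas)
  root <- taxRoot(taxonomy)
  nsRoots <- vapply(.NS_LEVELS, function(ns) {
    cand <- terms[ontology@termNamespace[terms] == ns]
    cand[!(cand %in% ontology@edges$child)][1]
  }, "")
  candTax <- setdiff(g, root)
  candTerm <- setdiff(terms, nsRoots)
  target <- frac * length(feas)
  tries <- 0L
  while (sum(!feas) < target && tries < 200L) {
    tries <- tries + 1L
    t0 <- sample(candTax, 1)
    g0 <- sample(candTerm, 1)
    tBlock <- intersect(taxDescendants(taxonomy, t0), g)
    gBlock <- termDescendants(ontology, g0)
    feas[tBlock, gBlock] <- FALSE
  }
  feas
}

#' Feasible / infeasible term sets of a general taxon
#'
#' @param world a [SyntheticWorld-class].
#' @param generalTaxon a general taxon id.
#' @return character vector of term ids.
#' @export
feasibleTerms <- function(world, generalTaxon) {
  colnames(world@feasibility)[world@feasibility[generalTaxon, ]]
}

#' @rdname feasibleTerms
#' @export
infeasibleTerms <- function(world, generalTaxon) {
  colnames(world@feasibility)[!world@feasibility[generalTaxon, ]]
}

#' Sample annotations from a synthetic world
#'
#' Emits GAF 2.1 text with known ground truth: proteins are attached to the
#' leaf taxa of the world's taxonomy, and each protein draws terms from the
#' feasible set of its general taxon. With probability `noiseRate` a draw
#' comes from the infeasible set instead (an annotation error); a fraction
#' `experimentalRate` of the *correct* records carries an experimental
#' evidence code (IDA), everything else IEA — annotation errors in real
#' corpora come almost exclusively from electronic transfer, so noisy
#' records are never experimentally evidenced. Deterministic given the
#' seed.
#'
#' @param world a [SyntheticWorld-class].
#' @param proteinsPerTaxon proteins generated for each leaf taxon.
#' @param noiseRate probability that an annotation is drawn from the
#'   infeasible set.
#' @param experimentalRate fraction of records with experimental evidence.
#' @param seed RNG seed.
#' @param meanTermsPerProtein mean number of annotations per protein
#'   (1 + Poisson).
#' @return character vector of GAF lines.
#' @export
sampleAnnotations <- function(world, proteinsPerTaxon = 50, noiseRate = 0.05,
                              experimentalRate = 0.1, seed = 1,
                              meanTermsPerProtein = 5) {
  stopifnot(noiseRate >= 0, noiseRate <= 1,
            experimentalRate >= 0, experimentalRate <= 1)
  tax <- world@taxonomy
  leaves <- setdiff(taxa(tax), tax@nodes$parent)
  rows <- .withSeed(seed, {
    acc <- list()
    pid <- 0L
    for (lf in leaves) {
      gt <- toGeneral(world@map, lf)
      okTerms <- feasibleTerms(world, gt)
      badTerms <- infeasibleTerms(world, gt)
      if (!length(okTerms)) {
        warning("leaf taxon ", lf, " has an empty feasible set; skipped")
        next
      }
      for (p in seq_len(proteinsPerTaxon)) {
        pid <- pid + 1L
        nAnn <- 1L + rpois(1, meanTermsPerProtein - 1)
        noisy <- runif(nAnn) < noiseRate & length(badTerms) > 0
        terms <- character(nAnn)
        if (any(!noisy)) terms[!noisy] <- sample(okTerms, sum(!noisy), replace = TRUE)
        if (any(noisy)) terms[noisy] <- sample(badTerms, sum(noisy), replace = TRUE)
        ev <- ifelse(!noisy & runif(nAnn) < experimentalRate, "IDA", "IEA")
        acc[[length(acc) + 1L]] <- data.frame(
          protein = sprintf("SYNP%06d", pid), go_id = terms, taxon = lf,
          evidence = ev, qualifier = "", db = "SYN",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, acc)
  })
  if (is.null(rows)) rows <- .emptyGafRecords()
  writeGAF(new("AnnotationSet", records = rows,
               dropped = c(not = 0L, unresolved_go = 0L, obsolete_go = 0L,
                           unresolved_taxon = 0L)))
}

#' Generate a synthetic similarity hit table
#'
#' Per query, `k` subject proteins are sampled from taxa outside the query
#' clade, with e-values drawn log-uniformly from `[1e-180, 1]`.
#' Deterministic given the seed.
#'
#' @param world a [SyntheticWorld-class].
#' @param annotations an [AnnotationSet-class] over the world (the subject
#'   pool and their taxa).
#' @param queryTaxon taxon id of the query organism.
#' @param nQueries number of query proteins.
#' @param k hits per query.
#' @param seed RNG seed.
#' @return data.frame (`query`, `subject`, `evalue`).
#' @export
generateHitTable <- function(world, annotations, queryTaxon, nQueries = 20,
                             k = 10, seed = 1) {
  stopifnot(k >= 1, nQueries >= 1)
  rec <- annotations(annotations)
  clade <- taxDescendants(world@taxonomy, queryTaxon)
  pool <- unique(rec$protein[!(rec$taxon %in% clade)])
  if (!length(pool))
    stop("parameter error: no foreign subject proteins available")
  .withSeed(seed, {
    query <- rep(sprintf("QRY%05d", seq_len(nQueries)), each = k)
    subject <- sample(pool, nQueries * k, replace = TRUE)
    evalue <- 10^(-runif(nQueries * k, 0, .SCORE_CAP))
    data.frame(query = query, subject = subject, evalue = evalue,
               stringsAsFactors = FALSE)
  })
}

#' Write the world's ground truth feasibility as TSV
#'
#' @param world a [SyntheticWorld-class].
#' @param file optional output path.
#' @return TSV lines (`taxon_id`, `go_id`, `feasible`), invisibly.
#' @export
writeFeasibility <- function(world, file = NULL) {
  f <- world@feasibility
  idx <- expand.grid(taxon = rownames(f), go_id = colnames(f),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- c("taxon_id\tgo_id\tfeasible",
           paste(idx$taxon, idx$go_id,
                 ifelse(f[cbind(idx$taxon, idx$go_id)], "1", "0"),
                 sep = "\t"))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
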
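## Fixture builders and independent brute-force oracles shared across tests.

## ---- tiny hand-written fixtures ----------------------------------------

## 5-term BP ontology with a diamond and an alt_id:
##   root GO:0000001; A GO:0000002 (alt GO:0000099); B GO:0000003;
##   C GO:0000004 is_a A, part_of B; D GO:0000005 is_a C
tinyOboText <- function() {
  paste(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: A", "alt_id: GO:0000099",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: B",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: C",
    "namespace: biological_process", "is_a: GO:0000002",
    "relationship: part_of GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: D",
    "namespace: biological_process", "is_a: GO:0000004", ""),
    collapse = "\n")
}

## taxonomy: root 1 > superkingdom 2 > class 3 > (species 4, species 5);
## plus class 6 under 2, species 7 under 6
tinyTaxonomy <- function() {
  nodes <- paste0(
    c("1\t|\t1\t|\tno rank\t|",
      "2\t|\t1\t|\tsuperkingdom\t|",
      "3\t|\t2\t|\tclass\t|",
      "4\t|\t3\t|\tspecies\t|",
      "5\t|\t3\t|\tspecies\t|",
      "6\t|\t2\t|\tclass\t|",
      "7\t|\t6\t|\tspecies\t|"), collapse = "\n")
  names <- paste0(
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "3\t|\tClassThree\t|\t\t|\tscientific name\t|",
      "3\t|\tOldThree\t|\t\t|\tsynonym\t|"), collapse = "\n")
  parseTaxdump(nodes, names)
}

gafLine <- function(protein = "P1", go = "GO:0000005", taxon = "4",
                    evidence = "IEA", qualifier = "") {
  paste("SYN", protein, protein, qualifier, go, "PMID:1", evidence, "",
        "P", "", "", "protein", paste0("taxon:", taxon), "20160101",
        "SYN", "", "", sep = "\t")
}

## ---- random structure generators ---------------------------------------

## random rooted tree as a reduced-tree data.frame (taxon, parent)
randomTree <- function(n) {
  parent <- c(NA_character_,
              paste0("t", vapply(seq_len(n - 1) + 1L,
                                 function(j) sample.int(j - 1L, 1L), 1L)))
  data.frame(taxon = paste0("t", seq_len(n)), parent = parent,
             stringsAsFactors = FALSE)
}

## random single-namespace DAG as an OntologyGraph; term 1 is the root
randomOntology <- function(nTerms, pExtraParent = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(nTerms))
  edges <- list()
  for (i in seq_len(nTerms)[-1]) {
    par <- ids[sample.int(i - 1L, 1L)]
    extra <- if (i > 2 && runif(1) < pExtraParent)
      ids[sample.int(i - 1L, 1L)] else character()
    pp <- unique(c(par, extra))
    edges[[i]] <- data.frame(child = ids[i], parent = pp,
                             type = sample(c("is_a", "part_of"), length(pp),
                                           replace = TRUE, prob = c(0.8, 0.2)),
                             stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edges)
  ed$type[match(unique(ed$child), ed$child)] <- "is_a"
  new("OntologyGraph", terms = ids,
      termName = setNames(ids, ids),
      termNamespace = setNames(rep("biological_process", nTerms), ids),
      obsolete = setNames(rep(FALSE, nTerms), ids),
      edges = ed, altMap = setNames(character(), character()),
      graph = taxonConstraints:::.buildTermGraph(ids, ed))
}

## random annotation records over an ontology and a set of taxa
randomAnnotations <- function(ontology, taxa, nProteins, maxTermsPerProtein = 3) {
  recs <- lapply(seq_len(nProteins), function(i) {
    terms <- sample(goTerms(ontology), sample.int(maxTermsPerProtein, 1L))
    data.frame(protein = sprintf("P%04d", i), go_id = terms,
               taxon = sample(taxa, 1L), evidence = "IEA", qualifier = "",
               db = "SYN", stringsAsFactors = FALSE)
  })
  new("AnnotationSet", records = do.call(rbind, recs),
      dropped = c(not = 0L, unresolved_go = 0L, obsolete_go = 0L,
                  unresolved_taxon = 0L))
}

## ---- independent oracles ------------------------------------------------

## descendant set by naive edge scanning (no igraph)
oracleDescendants <- function(ontology, g) {
  ed <- ontology@edges
  out <- g
  repeat {
    new <- setdiff(ed$child[ed$parent %in% out], out)
    if (!length(new)) return(out)
    out <- c(out, new)
  }
}

oracleAncestors <- function(ontology, g) {
  ed <- ontology@edges
  out <- g
  repeat {
    new <- setdiff(ed$parent[ed$child %in% out], out)
    if (!length(new)) return(out)
    out <- c(out, new)
  }
}

## brute-force cumulative distinct-protein counts: for each term scan its
## descendant closure and tally distinct proteins per taxon
oracleCounts <- function(records, ontology) {
  terms <- goTerms(ontology)
  ctg <- list()
  cg <- setNames(integer(length(terms)), terms)
  for (g in terms) {
    dset <- oracleDescendants(ontology, g)
    hit <- records[records$go_id %in% dset, , drop = FALSE]
    cg[g] <- length(unique(hit$protein))
    if (nrow(hit)) {
      tab <- tapply(hit$protein, hit$taxon, function(x) length(unique(x)))
      ctg[[g]] <- data.frame(taxon = names(tab), go_id = g,
                             c_tg = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  list(ctg = do.call(rbind, ctg), cg = cg)
}

## world + clean/noisy annotations + full inference, shared by several tests
runSyntheticPipeline <- function(seed, nTerms = 40, nTaxa = 20,
                                 proteinsPerTaxon = 40, noiseRate = 0,
                                 experimentalRate = 0.3, cutoff = 30,
                                 infeasibleFraction = 0.25, depth = 4) {
  world <- generateWorld(nTerms, nTaxa, depth, infeasibleFraction, seed = seed)
  gaf <- sampleAnnotations(world, proteinsPerTaxon, noiseRate,
                           experimentalRate, seed = seed + 1)
  ann <- parseGAF(gaf, world@ontology, world@taxonomy)
  res <- inferConstraints(world@ontology, world@taxonomy, ann,
                          groups = groupSpecFromRanks(world@taxonomy),
                          autoReference = TRUE, cutoff = cutoff,
                          details = TRUE)
  c(list(world = world, annotations = ann), res)
}
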
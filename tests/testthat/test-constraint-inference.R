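mkAnn <- function(rec) {
  if (is.null(rec$evidence)) rec$evidence <- "IEA"
  new("AnnotationSet",
      records = data.frame(protein = rec$protein, go_id = rec$go_id,
                           taxon = rec$taxon, evidence = rec$evidence,
                           qualifier = "", db = "S",
                           stringsAsFactors = FALSE),
      dropped = c(not = 0L, unresolved_go = 0L, obsolete_go = 0L,
                  unresolved_taxon = 0L))
}

test_that("cumulative counts use distinct-protein closure semantics", {
  g <- parseOBO(tinyOboText())
  tax <- tinyTaxonomy()
  map <- buildGeneralTaxonMap(tax)
  ## a protein annotated with the leaf D counts once for every ancestor
  ann <- mkAnn(list(protein = "P1", go_id = "GO:0000005", taxon = "4"))
  ct <- cumulativeTermCounts(ann, g, map)
  for (term in c("GO:0000005", "GO:0000004", "GO:0000003", "GO:0000002",
                 "GO:0000001"))
    expect_identical(taxonConstraints:::.lookupCtg(ct, "3", term), 1L)
  ## a protein annotated with both C and its child D still counts once
  ann <- mkAnn(list(protein = "P1", go_id = c("GO:0000004", "GO:0000005"),
                    taxon = "4"))
  ct <- cumulativeTermCounts(ann, g, map)
  expect_identical(taxonConstraints:::.lookupCtg(ct, "3", "GO:0000004"), 1L)
  expect_identical(unname(ct@cg[["GO:0000004"]]), 1L)
  ## two proteins of different general taxa split c_tg but sum in c_g
  ann <- mkAnn(list(protein = c("P1", "P2"), go_id = "GO:0000004",
                    taxon = c("4", "7")))
  ct <- cumulativeTermCounts(ann, g, map)
  expect_identical(unname(ct@cg[["GO:0000004"]]), 2L)
  expect_identical(taxonConstraints:::.lookupCtg(ct, "3", "GO:0000004"), 1L)
  expect_identical(taxonConstraints:::.lookupCtg(ct, "6", "GO:0000004"), 1L)
})

test_that("counts match the brute-force closure oracle on random DAGs", {
  set.seed(23)
  for (rep in 1:40) {
    g <- randomOntology(sample(5:40, 1))
    ann <- randomAnnotations(g, paste0("t", 1:4), sample(5:40, 1))
    ## identity map: every taxon is its own general taxon
    ids <- paste0("t", 1:4)
    map <- new("GeneralTaxonMap", generalTaxa = ids,
               mapping = setNames(ids, ids))
    ct <- cumulativeTermCounts(ann, g, map)
    orc <- oracleCounts(annotations(ann), g)
    expect_identical(ct@cg[names(orc$cg)][orc$cg > 0], orc$cg[orc$cg > 0])
    got <- ct@ctg[order(ct@ctg$taxon, ct@ctg$go_id), ]
    want <- orc$ctg[order(orc$ctg$taxon, orc$ctg$go_id), ]
    expect_equal(got, want, ignore_attr = TRUE)
    ## monotone up the DAG (terms absent from cg have zero cumulative count)
    cgAll <- setNames(rep(0L, length(goTerms(g))), goTerms(g))
    cgAll[names(ct@cg)] <- ct@cg
    expect_true(all(cgAll[g@edges$parent] >= cgAll[g@edges$child]))
  }
})

test_that("frequent-term selection keeps the boundary value", {
  ct <- new("CountTable",
            ctg = data.frame(taxon = character(), go_id = character(),
                             c_tg = integer()),
            cg = c("GO:1" = 500L, "GO:2" = 499L, "GO:3" = 12L),
            cAt = data.frame(namespace = character(), taxon = character(),
                             c_At = integer()),
            cA = setNames(integer(), character()),
            nsMap = setNames(character(), character()))
  expect_identical(selectFrequentTerms(ct, 500), "GO:1")
  expect_setequal(selectFrequentTerms(ct, 0), c("GO:1", "GO:2", "GO:3"))
})

test_that("relative probability is the taxon frequency over the global frequency", {
  ct <- new("CountTable",
            ctg = data.frame(taxon = "t1", go_id = "GO:1", c_tg = 8L),
            cg = c("GO:1" = 16L),
            cAt = data.frame(namespace = "biological_process", taxon = "t1",
                             c_At = 10L),
            cA = c(biological_process = 100L),
            nsMap = c("GO:1" = "biological_process"))
  ## (8/10) / (16/100) = 5
  expect_equal(relativeProbability(ct, "t1", "GO:1"), 5.0)
  ## whole-dataset taxon: P_rel = 1
  ct@ctg$c_tg <- 16L; ct@cAt$c_At <- 100L
  expect_equal(relativeProbability(ct, "t1", "GO:1"), 1.0)
  ## zero c_tg with positive c_At
  ct@ctg$c_tg <- 0L; ct@cAt$c_At <- 10L
  expect_equal(relativeProbability(ct, "t1", "GO:1"), 0)
})

test_that("polarity labels follow the closed/open world rule and overrides", {
  ct <- new("CountTable",
            ctg = data.frame(taxon = c("rob", "open"), go_id = "GO:1",
                             c_tg = c(0L, 0L)),
            cg = c("GO:1" = 50L),
            cAt = data.frame(namespace = "biological_process",
                             taxon = c("rob", "open"), c_At = c(40L, 40L)),
            cA = c(biological_process = 100L),
            nsMap = c("GO:1" = "biological_process"))
  pol <- assignPolarity(ct, frequent = "GO:1", robust = "rob",
                        extraTaxa = "open")
  ## robust taxon with no proteins: closed world -> negative
  expect_identical(pol$label[pol$taxon == "rob"], "negative")
  expect_identical(pol$polarity[pol$taxon == "rob"], -1)
  ## non-robust taxon: open world -> neutral
  expect_identical(pol$label[pol$taxon == "open"], "neutral")
  ## one experimental record forces positive despite zero frequency
  pol2 <- assignPolarity(ct, "GO:1", "rob",
                         experimental = data.frame(taxon = "rob",
                                                   go_id = "GO:1"))
  expect_identical(pol2$label[pol2$taxon == "rob"], "positive")
  expect_true(pol2$has_experimental[pol2$taxon == "rob"])
  expect_error(assignPolarity(ct, "GO:1", "rob", thetaNeg = 0.5,
                              thetaPos = 0.2), "theta")
})

test_that("labels are monotone in the relative probability", {
  mk <- function(ctg) new("CountTable",
    ctg = data.frame(taxon = "t", go_id = "GO:1", c_tg = as.integer(ctg)),
    cg = c("GO:1" = 100L),
    cAt = data.frame(namespace = "biological_process", taxon = "t",
                     c_At = 100L),
    cA = c(biological_process = 400L),
    nsMap = c("GO:1" = "biological_process"))
  ord <- c(negative = 1, neutral = 2, positive = 3)
  labels <- vapply(seq(0, 100, by = 5), function(k)
    assignPolarity(mk(k), "GO:1", "t")$label, "")
  expect_true(all(diff(ord[labels]) >= 0))
  ## an added experimental record can only move a label towards positive
  for (k in c(0, 10, 40, 90)) {
    base <- assignPolarity(mk(k), "GO:1", "t")$label
    over <- assignPolarity(mk(k), "GO:1", "t",
                           experimental = data.frame(taxon = "t",
                                                     go_id = "GO:1"))$label
    expect_gte(ord[[over]], ord[[base]])
  }
})

test_that("bootstrap p-values are deterministic, degenerate cases exact", {
  g <- parseOBO(tinyOboText())
  tax <- tinyTaxonomy()
  map <- buildGeneralTaxonMap(tax)
  ## every protein of the taxon supports the term: no replicate can flip it
  ann <- mkAnn(list(protein = paste0("P", 1:12), go_id = "GO:0000005",
                    taxon = "4"))
  ct <- cumulativeTermCounts(ann, g, map)
  pol <- assignPolarity(ct, frequent = c("GO:0000005", "GO:0000001"),
                        robust = "3")
  pv <- bootstrapPvalues(ann, pol, ct, g, map, nReps = 50, seed = 9)
  expect_true(all(pv$p_value == 0))
  pv2 <- bootstrapPvalues(ann, pol, ct, g, map, nReps = 50, seed = 9)
  expect_identical(pv2$p_value, pv$p_value)
  ## nReps = 1 gives a 0/1 p-value
  pv1 <- bootstrapPvalues(ann, pol, ct, g, map, nReps = 1, seed = 3)
  expect_true(all(pv1$p_value %in% c(0, 1)))
})

test_that("a borderline label flips in half the replicates (binomial oracle)", {
  ## Two unrelated BP terms A and B. The scored taxon (class 3) has two
  ## proteins, one annotated with A; globally c_A = 10 proteins, c_g(A) = 5,
  ## so the original P_rel(3, A) = (1/2)/(5/10) = 1 -> neutral.
  ## Resampling the two proteins, the support count X ~ Binomial(2, 1/2):
  ##   X = 0 -> closed-world negative (flip),
  ##   X = 1 -> P_rel = 1, neutral (no flip),
  ##   X = 2 -> P_rel = 2, polarity 1/3 >= 0.2, positive (flip);
  ## the exact flip probability is therefore 1/2.
  obo <- paste("[Term]\nid: GO:0000001\nname: A",
               "namespace: biological_process\n",
               "[Term]\nid: GO:0000002\nname: B",
               "namespace: biological_process", sep = "\n")
  g <- parseOBO(obo)
  tax <- tinyTaxonomy()
  map <- buildGeneralTaxonMap(tax)
  ann <- mkAnn(list(
    protein = c("P1", "P2", paste0("Q", 1:8)),
    go_id = c("GO:0000001", "GO:0000002",
              rep(c("GO:0000001", "GO:0000002"), each = 4)),
    taxon = c("4", "4", rep("7", 8))))
  ct <- cumulativeTermCounts(ann, g, map)
  pol <- assignPolarity(ct, frequent = "GO:0000001", robust = "3")
  expect_identical(pol$label, "neutral")
  nReps <- 1000
  pv <- bootstrapPvalues(ann, pol, ct, g, map, nReps = nReps, seed = 42)
  sigma <- sqrt(0.5 * 0.5 / nReps)
  expect_lt(abs(pv$p_value - 0.5), 3 * sigma)
})
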
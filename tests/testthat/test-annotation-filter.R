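## fixture: tiny ontology + taxonomy, subjects with known terms
filterWorld <- function() {
  g <- parseOBO(tinyOboText())
  tax <- tinyTaxonomy()
  ann <- new("AnnotationSet", records = data.frame(
    protein = c("S1", "S1", "S2", "S3"),
    go_id = c("GO:0000004", "GO:0000003", "GO:0000005", "GO:0000002"),
    taxon = c("5", "5", "5", "7"),
    evidence = "IEA", qualifier = "", db = "S", stringsAsFactors = FALSE),
    dropped = c(not = 0L, unresolved_go = 0L, obsolete_go = 0L,
                unresolved_taxon = 0L))
  list(g = g, tax = tax, ann = ann, map = buildGeneralTaxonMap(tax))
}

test_that("hit transfer scores terms by capped -log10 e-value, max over hits", {
  w <- filterWorld()
  ## one hit at 1e-50 with two GO terms -> two predictions at score 50
  hits <- data.frame(query = "Q1", subject = "S1", evalue = 1e-50)
  p <- transferFromHits(hits, w$ann, w$tax)
  expect_identical(nrow(p), 2L)
  expect_true(all(p$score == 50))
  ## the same term reached at 1e-10 and 1e-40 keeps the max score
  hits <- data.frame(query = c("Q1", "Q1"), subject = c("S1", "S1"),
                     evalue = c(1e-10, 1e-40))
  p <- transferFromHits(hits, w$ann, w$tax)
  expect_identical(nrow(p), 2L)
  expect_true(all(p$score == 40))
  ## e-value 0 is capped, not infinite
  hits <- data.frame(query = "Q1", subject = "S2", evalue = 0)
  p <- transferFromHits(hits, w$ann, w$tax)
  expect_identical(p$score, 180)
  ## clade exclusion drops subjects before truncation
  hits <- data.frame(query = "Q1", subject = c("S1", "S2"),
                     evalue = c(1e-5, 1e-80))
  p <- transferFromHits(hits, w$ann, w$tax, excludeClade = "3")
  expect_identical(nrow(p), 0L)
  ## truncation to k by ascending e-value
  hits <- data.frame(query = "Q1", subject = c("S3", "S2"),
                     evalue = c(1e-90, 1e-5))
  p <- transferFromHits(hits, w$ann, w$tax, k = 1)
  ## only the best hit S3 (GO:0000002) survives
  expect_identical(p$go_id, "GO:0000002")
})

test_that("constraint filtering removes never_in always, neutral only closed-world", {
  w <- filterWorld()
  preds <- data.frame(go_id = c("GO:0000002", "GO:0000003", "GO:0000005"),
                      score = c(10, 20, 30), n_subjects = 1L)
  cs <- constraintSet(data.frame(
    go_id = c("GO:0000002", "GO:0000005"), taxon_id = "3",
    state = c("in", "never_in"), source = "manual"))
  open <- applyConstraints(preds, cs, w$map, "4", world = "open")
  expect_setequal(open$go_id, c("GO:0000002", "GO:0000003"))
  expect_identical(attr(open, "removed")$go_id, "GO:0000005")
  closed <- applyConstraints(preds, cs, w$map, "4", world = "closed")
  expect_identical(closed$go_id, "GO:0000002")
  ## dubious behaves like neutral at filter time
  cs2 <- constraintSet(data.frame(go_id = "GO:0000003", taxon_id = "3",
                                  state = "dubious", source = "manual"))
  open2 <- applyConstraints(preds, cs2, w$map, "4", world = "open")
  expect_true("GO:0000003" %in% open2$go_id)
  closed2 <- applyConstraints(preds, cs2, w$map, "4", world = "closed")
  expect_false("GO:0000003" %in% closed2$go_id)
  ## empty constraint set in open world is the identity
  empty <- constraintSet(data.frame(go_id = character(), taxon_id = character(),
                                    state = character(), source = character()))
  same <- applyConstraints(preds, empty, w$map, "4", world = "open")
  expect_identical(same$go_id, preds$go_id)
  ## closed-world output is a subset of open-world output
  expect_true(all(closed$go_id %in% open$go_id))
})

test_that("back-off replaces a banned term with its nearest allowed ancestor", {
  w <- filterWorld()
  preds <- data.frame(go_id = "GO:0000005", score = 33, n_subjects = 1L)
  cs <- constraintSet(data.frame(
    go_id = c("GO:0000005", "GO:0000004"), taxon_id = "3",
    state = "never_in", source = "manual"))
  out <- applyConstraints(preds, cs, w$map, "4", world = "open",
                          ontology = w$g, backoff = TRUE)
  ## D and C are banned; the nearest allowed ancestors are A/B one level up
  expect_identical(out$go_id, "GO:0000002")
  expect_identical(out$score, 33)
})

test_that("GO-centric evaluation closes both sides and bins by inherited max score", {
  g <- parseOBO(tinyOboText())
  bins <- c(0, 25, 50)
  ## predicted leaf in gold: leaf and all ancestors are TP
  preds <- data.frame(go_id = "GO:0000005", score = 30)
  ev <- evaluateGOCentric(preds, "GO:0000005", g, bins)
  expect_identical(sum(ev$tp), 5L)
  expect_identical(sum(ev$fp), 0L)
  expect_identical(ev$tp[2], 5L)  # closure members inherit the leaf score
  ## predicted sibling of a gold term: sibling FP, shared parent TP
  obo7 <- paste(tinyOboText(),
                "[Term]\nid: GO:0000006\nname: E",
                "namespace: biological_process\nis_a: GO:0000004\n",
                sep = "\n")
  g7 <- parseOBO(obo7)
  preds <- data.frame(go_id = "GO:0000006", score = 10)
  ev <- evaluateGOCentric(preds, "GO:0000005", g7, bins)
  ## closure of prediction: E + C + A + B + root; gold closure contains all
  ## but E
  expect_identical(sum(ev$fp), 1L)
  expect_identical(sum(ev$tp), 4L)
  ## no predictions: zero-filled bins
  ev0 <- evaluateGOCentric(preds[0, ], "GO:0000005", g, bins)
  expect_true(all(ev0$tp == 0L) && all(ev0$fp == 0L))
  ## duplicate predictions do not change the tally (non-redundancy)
  dup <- data.frame(go_id = c("GO:0000005", "GO:0000005"), score = c(30, 12))
  ev1 <- evaluateGOCentric(dup, "GO:0000005", g, bins)
  ev2 <- evaluateGOCentric(data.frame(go_id = "GO:0000005", score = 30),
                           "GO:0000005", g, bins)
  expect_identical(ev1, ev2)
  ## empty gold warns and counts everything FP
  expect_warning(evF <- evaluateGOCentric(data.frame(go_id = "GO:0000005",
                                                     score = 30),
                                          character(), g, bins), "gold")
  expect_identical(sum(evF$fp), 5L)
})

test_that("hit tables round-trip and accept blast outfmt-6 layouts", {
  h <- data.frame(query = c("Q1", "Q2"), subject = c("S1", "S2"),
                  evalue = c(1e-30, 2e-7))
  back <- readHitTable(paste(writeHitTable(h), collapse = "\n"))
  expect_identical(back$query, h$query)
  expect_equal(back$evalue, h$evalue, tolerance = 1e-6)
  ## 12-column blast line: e-value sits in column 11
  line <- "Q1\tS1\t97.1\t120\t3\t0\t1\t120\t5\t124\t4e-55\t201"
  b <- readHitTable(line)
  expect_equal(b$evalue, 4e-55)
})

test_that("filtering is monotone: closed subset of open subset of unfiltered", {
  set.seed(17)
  for (rep in 1:5) {
    res <- runSyntheticPipeline(seed = 60 + rep, nTerms = 30, nTaxa = 16,
                                proteinsPerTaxon = 20, noiseRate = 0.1,
                                cutoff = 10)
    w <- res$world
    leaves <- setdiff(taxa(w@taxonomy), w@taxonomy@nodes$parent)
    target <- leaves[1]
    hits <- generateHitTable(w, res$annotations, target, nQueries = 10,
                             k = 5, seed = rep)
    preds <- transferFromHits(hits, res$annotations, w@taxonomy)
    open <- applyConstraints(preds, res$constraints, res$map, target, "open")
    closed <- applyConstraints(preds, res$constraints, res$map, target,
                               "closed")
    expect_true(all(closed$go_id %in% open$go_id))
    expect_true(all(open$go_id %in% preds$go_id))
    ## per-bin counts are monotone as well
    bins <- seq(0, 180, by = 45)
    gold <- unique(annotations(res$annotations)$go_id[
      annotations(res$annotations)$taxon == target])
    evAll <- evaluateGOCentric(preds, gold, w@ontology, bins)
    evOpen <- evaluateGOCentric(open, gold, w@ontology, bins)
    evClosed <- evaluateGOCentric(closed, gold, w@ontology, bins)
    ## removal can only shift closure members to lower bins, so the count
    ## of terms at or above any score threshold is monotone
    cum <- function(ev) rev(cumsum(rev(ev$tp + ev$fp)))
    expect_true(all(cum(evOpen) <= cum(evAll)))
    expect_true(all(cum(evClosed) <= cum(evOpen)))
  }
})
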
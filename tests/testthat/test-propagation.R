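## convenience: run the sweep on a (state, frozen) seeding of a tree
sweep0 <- function(seed, frozen, tree) sweepTaxonomyFixpoint(seed, frozen, tree)

test_that("tree rules I-IV behave as specified on hand-built trees", {
  star <- data.frame(taxon = c("r", "a", "b", "c"),
                     parent = c(NA, "r", "r", "r"))
  ## Rule I: polar children propagate to the neutral parent
  expect_identical(sweep0(c(0, 1, 1, 0), c(FALSE, TRUE, TRUE, FALSE), star),
                   c(1L, 1L, 1L, 1L))
  ## Rule II: a polar parent propagates to all neutral children
  expect_identical(sweep0(c(1, 0, 0, 0), c(TRUE, FALSE, FALSE, FALSE), star),
                   c(1L, 1L, 1L, 1L))
  ## Rule III: opposite siblings -> parent ambiguous, neutral sibling too
  expect_identical(sweep0(c(0, 1, -1, 0), c(FALSE, TRUE, TRUE, FALSE), star),
                   c(2L, 1L, -1L, 2L))
  ## Rule IV: polar parent + opposite child -> neutral child ambiguous
  tri <- data.frame(taxon = c("p", "c1", "c2"), parent = c(NA, "p", "p"))
  expect_identical(sweep0(c(1, -1, 0), c(TRUE, TRUE, FALSE), tri),
                   c(1L, -1L, 2L))
  ## no spontaneous polarity
  expect_identical(sweep0(rep(0, 4), rep(FALSE, 4), star), rep(0L, 4))
})

test_that("sweep fixed point equals chaotic iteration and is idempotent", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(3:50, 1)
    tr <- randomTree(n)
    seed <- integer(n)
    frozen <- rep(FALSE, n)
    idx <- sample.int(n, sample.int(min(10L, n), 1))
    seed[idx] <- sample(c(-1L, 1L), length(idx), replace = TRUE)
    frozen[idx] <- TRUE
    sw <- sweepTaxonomyFixpoint(seed, frozen, tr)
    ## seed immutability
    expect_identical(sw[idx], seed[idx])
    ## confluence over random schedules
    for (k in 1:5)
      expect_identical(chaoticTaxonomyFixpoint(seed, frozen, tr), sw)
    ## idempotence: feeding the fixed point back (all non-neutral frozen)
    ## changes nothing
    expect_identical(sweepTaxonomyFixpoint(sw, sw != 0L, tr), sw)
  }
})

test_that("propagateTaxonomy handles seeds per term and keeps sources", {
  tree <- data.frame(taxon = c("r", "a", "b"), parent = c(NA, "r", "r"))
  seeds <- data.frame(taxon = c("a", "b"), go_id = "GO:0000001",
                      label = c("positive", "positive"),
                      n_proteins = c(5L, 2L))
  st <- propagateTaxonomy(seeds, tree)
  expect_identical(st$state[st$taxon == "r"], 1L)
  expect_identical(st$source[st$taxon == "r"], "taxon_propagation")
  expect_identical(st$source[st$taxon == "a"], "frequency")
  expect_true(all(st$frozen[st$taxon %in% c("a", "b")]))
})

test_that("GO closure sends positives up and negatives down, conflicts to ambiguous", {
  g <- parseOBO(tinyOboText())
  ## never_in at C descends to D
  st <- data.frame(go_id = "GO:0000004", taxon = "t", state = -1L,
                   frozen = TRUE, source = "frequency")
  out <- propagateGO(st, g)
  expect_identical(out$state[out$go_id == "GO:0000005"], -1L)
  expect_identical(out$source[out$go_id == "GO:0000005"], "go_propagation")
  ## in at D ascends through C to A, B and the root
  st <- data.frame(go_id = "GO:0000005", taxon = "t", state = 1L,
                   frozen = TRUE, source = "frequency")
  out <- propagateGO(st, g)
  expect_setequal(out$go_id[out$state == 1L], sprintf("GO:%07d", 1:5))
  ## positive and negative meeting on the same term -> ambiguous
  st <- data.frame(go_id = c("GO:0000005", "GO:0000002"), taxon = "t",
                   state = c(1L, -1L), frozen = TRUE, source = "frequency")
  out <- propagateGO(st, g)
  ## C and D descend from A (negative) but D also pushes positives up
  ## through C: both closures meet on C
  expect_identical(out$state[out$go_id == "GO:0000004"], 2L)
  ## frozen seeds keep their state even inside the opposite closure
  expect_identical(out$state[out$go_id == "GO:0000005"], 1L)
  expect_identical(out$state[out$go_id == "GO:0000002"], -1L)
})

test_that("GO closure matches a brute-force reachability oracle on random DAGs", {
  set.seed(31)
  for (rep in 1:30) {
    g <- randomOntology(sample(6:12, 1))
    terms <- goTerms(g)
    k <- sample(2:4, 1)
    pick <- sample(terms, k)
    stt <- sample(c(1L, -1L), k, replace = TRUE)
    st <- data.frame(go_id = pick, taxon = "t", state = stt,
                     frozen = FALSE, source = "frequency")
    out <- propagateGO(st, g)
    ## oracle: union of ancestor closures of positives and descendant
    ## closures of negatives via naive edge scans
    pos <- unique(unlist(lapply(pick[stt == 1L], function(x)
      oracleAncestors(g, x))))
    neg <- unique(unlist(lapply(pick[stt == -1L], function(x)
      oracleDescendants(g, x))))
    want <- setNames(rep(0L, length(terms)), terms)
    want[setdiff(pos, neg)] <- 1L
    want[setdiff(neg, pos)] <- -1L
    want[intersect(pos, neg)] <- 2L
    got <- setNames(rep(0L, length(terms)), terms)
    got[out$go_id] <- out$state
    expect_identical(got, want)
  }
})

test_that("GO closure is idempotent and never assigns to obsolete terms", {
  g <- parseOBO(paste(tinyOboText(),
                      "[Term]\nid: GO:0000007\nname: dead",
                      "namespace: biological_process\nis_obsolete: true\n",
                      sep = "\n"))
  st <- data.frame(go_id = "GO:0000002", taxon = "t", state = -1L,
                   frozen = TRUE, source = "frequency")
  out <- propagateGO(st, g)
  expect_false("GO:0000007" %in% out$go_id)
  again <- propagateGO(out, g)
  o <- function(x) x[order(x$go_id, x$taxon), c("go_id", "taxon", "state")]
  expect_equal(o(again), o(out), ignore_attr = TRUE)
})

test_that("only_in translates to never_in exactly on disjoint general taxa", {
  ## toy reduced tree: root with two superkingdom subtrees
  tree <- data.frame(
    taxon = c("r", "E", "E1", "E2", "B", "B1"),
    parent = c(NA, "r", "E", "E", "r", "B"))
  ids <- tree$taxon
  map <- new("GeneralTaxonMap", generalTaxa = ids,
             mapping = setNames(ids, ids))
  tr <- data.frame(go_id = "GO:0032501", relation = "only_in",
                   taxon_id = "E")
  cs <- translateOnlyIn(tr, tree, map)
  r <- constraints(cs)
  expect_identical(r$state[r$taxon_id == "E"], "in")
  ## disjoint = everything outside E's ancestors and subtree
  expect_setequal(r$taxon_id[r$state == "never_in"], c("B", "B1"))
  expect_true(all(r$source == "manual"))
  ## never_in passes through untouched
  cs2 <- translateOnlyIn(data.frame(go_id = "GO:0032501",
                                    relation = "never_in", taxon_id = "E1"),
                         tree, map)
  expect_identical(constraints(cs2)$state, "never_in")
  expect_identical(constraints(cs2)$taxon_id, "E1")
  ## only_in at the root bans nothing
  cs3 <- translateOnlyIn(data.frame(go_id = "GO:0032501",
                                    relation = "only_in", taxon_id = "r"),
                         tree, map)
  expect_identical(constraints(cs3)$state, "in")
  expect_error(translateOnlyIn(data.frame(go_id = "GO:1", relation = "only_in",
                                          taxon_id = "nope"), tree, map),
               "unknown taxon")
})

test_that("combineSets lets the primary set win and logs conflicts", {
  g <- parseOBO(tinyOboText())
  a <- constraintSet(data.frame(go_id = "GO:0000004", taxon_id = "t",
                                state = "never_in", source = "manual"))
  b <- constraintSet(data.frame(go_id = c("GO:0000004", "GO:0000003"),
                                taxon_id = "t", state = c("in", "in"),
                                source = "frequency"))
  out <- combineSets(a, b, g)
  r <- constraints(out)
  expect_identical(r$state[r$go_id == "GO:0000004" & r$taxon_id == "t"],
                   "never_in")
  expect_identical(nrow(attr(out, "conflicts")), 1L)
  ## the secondary-only record survives and is re-closed upward
  expect_identical(r$state[r$go_id == "GO:0000003"], "in")
  expect_identical(r$state[r$go_id == "GO:0000001"], "in")
  ## identical states: no conflict
  out2 <- combineSets(a, a, g)
  expect_identical(nrow(attr(out2, "conflicts")), 0L)
})
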
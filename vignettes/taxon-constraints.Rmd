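---
title: "Inferring GO taxon constraints from annotation frequencies"
author: "taxonConstraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring GO taxon constraints from annotation frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxonConstraints)
```

## The problem

Gene Ontology (GO) terms are nominally species-independent, but many
functions exist only in parts of the tree of life: a fungus can synthesise
lysine through a pathway mammals lack entirely. A *taxon constraint* makes
this explicit — an **in** constraint says a term may annotate gene products
of a taxon and its descendants, a **never_in** constraint forbids it. Hand
curation covers only a small part of the ~40,000-term ontology, yet
automatically transferred annotations routinely violate taxonomic
plausibility (muscle or synapse terms predicted for yeast proteins, for
example). This package infers constraints automatically, at scale, from the
frequencies with which terms and taxa co-occur in an annotation corpus, and
uses them to filter taxonomically impossible predictions.

## The inference model

### Reduction to general taxa

Individual species are too sparsely and too unevenly annotated to support
per-species statistics, and closely related species share most of their
functional repertoire. The taxonomy is therefore collapsed to **general
taxa**: nodes of rank *class* or above in the NCBI rank ladder. Every taxon
maps to its most specific general ancestor-or-self (`buildGeneralTaxonMap()`);
nodes ranked `no rank` are transparent during the walk, and taxa with no
ranked ancestor at class level or above fall back to the root. Ranks missing
from the NCBI dump can be supplied through a rank-override table, which
replaces lookups into external taxonomies with a reproducible input file.

### Robust general taxa

Absence of evidence is only evidence of absence for well-studied taxa. To
decide which general taxa are well studied, the tree is partitioned into
kingdom-level groups (the shipped spec has seven: Amoebozoa, Archaea,
Bacteria, Chordata, Fungi, Metazoa excluding Chordata, Viridiplantae, with
Metazoa split so that the chordates do not dwarf the invertebrates). Inside
each group a reference taxon is fixed — either named in the spec or, with
`autoReference = TRUE`, the member with the most distinct GO ids, ties
broken towards the smaller taxon id for determinism. A member is **robust**
when its distinct-term count strictly exceeds 75% of the reference's
(`selectRobustTaxa()`; the threshold is a parameter, and the strict
inequality means a candidate at exactly 75% is not robust).

### Association statistics

All counts are distinct-protein counts, cumulative over the GO DAG: a
protein annotated with any `is_a`/`part_of` descendant of `g` counts once
towards `g` (`cumulativeTermCounts()`). With `c_tg` the proteins of general
taxon `t` annotated with `g` or a descendant, `c_g` the same count over the
whole corpus, and `c_At` / `c_A` the per-taxon and corpus-wide numbers of
proteins with at least one annotation in `g`'s sub-ontology `A`, the
relative probability of association is

$$P_{rel}(t,g) = \frac{c_{t,g}/{}^{A}c_{t}}{c_{g}/{}^{A}c}$$

— the taxon's usage frequency of the term normalised by the global usage
frequency, 1 when the taxon behaves like the corpus at large. Terms whose
cumulative corpus frequency `c_g` falls below a cutoff (default 500) are
not scored directly; the propagation stages later recover many of them.

### Polarities

`assignPolarity()` maps `P_rel` monotonely onto $[-1, +1)$ with
$pol = (P_{rel}-1)/(P_{rel}+1)$ and labels each (robust taxon, frequent
term) pair **positive** at `pol >= 0.2`, **negative** at `pol <= -0.6`, and
**neutral** between. The asymmetry is deliberate: claiming a function is
absent from a clade is a stronger statement than claiming it present, so
the negative region is kept away from the neutral band. Both thresholds are
exposed as parameters. Two special rules sit on top of the transform:

* **closed vs. open world.** When `c_tg = 0`, a robust taxon earns a
  negative polarity (a well-studied clade with no occurrence of the
  function presumably lacks it) while a non-robust taxon stays neutral —
  silence from an understudied clade proves nothing.
* **experimental override.** Any experimentally evidenced annotation of the
  term or a descendant in the taxon forces the label positive regardless of
  frequency: curated evidence outranks statistics. The default evidence
  list (EXP, IDA, IPI, IMP, IGI, IEP, the HTP family, TAS, IC) is wider
  than the strictly experimental codes because the point is "a curator
  vouched for this", and it is configurable.

Degenerate denominators (`c_At = 0` or `c_g = 0`) make `P_rel` undefined;
these cells are routed through the zero-count policy above rather than
producing infinities.

### Statistical support

`bootstrapPvalues()` attaches a support value to each seed label: the
taxon's proteins are resampled with replacement (the protein is the
resampling unit, because the annotations of one protein are not
independent; a protein drawn twice counts twice), the label is recomputed
under identical rules with corpus-level counts held fixed, and the p-value
is the fraction of replicates whose label differs. A label supported by
every protein has p = 0; a knife-edge label hovers near 0.5. Identical
inputs and seed give identical p-values.

## Propagation

### Over the taxonomic tree

Seed polarities live on robust general taxa only; four local rules extend
them over the reduced tree (`propagateTaxonomy()`):

* **I** — concordant polar children polarise their neutral parent;
* **II** — a polar parent polarises its neutral children;
* **III** — siblings of opposite polarity (or an ambiguous sibling) make
  the neutral parent and the neutral siblings ambiguous;
* **IV** — a polar parent with a child of opposite polarity leaves its
  other neutral children ambiguous rather than inheriting.

Seeds are frozen and never change; *ambiguous* (exported as `dubious`, the
two words describe the same state) is absorbing.

A subtle point is the order of rule application. Read naively, the rules
are order-sensitive: a node squeezed between a positive ancestor and a
negative descendant would end up with whichever polarity happened to reach
it first. We therefore interpret the rules as recomputations over two
separate information channels: a *subtree* channel (what a node's own
descendants support — rules I and III), and a *context* channel (what the
node inherits from above — rules II and IV, plus the descent of
ambiguity). Child-driven rules never read context-derived states, so
information cannot echo back up the tree; both channels are monotone
closures and every exhaustive application order reaches the same fixed
point. The deterministic schedule is one bottom-up sweep followed by one
top-down sweep, iterated to stability; `chaoticTaxonomyFixpoint()` applies
the same recomputations in a random order, and the test suite asserts on
hundreds of random instances that the two schedules agree, that seeds are
preserved, and that re-application is idempotent. Subtree evidence
deliberately outranks context: a clade whose own data say "absent" keeps
its negative even under a positive ancestor (the ancestor's other children
then see rule IV).

One consequence of the channel design: an ambiguous parent leaves its
neutral children ambiguous too. The rules only state this for siblings of a
conflicting pair; extending it downward keeps "no decision was made"
honest — a neutral child under a dubious parent would otherwise look like
an open question the method had actually examined.

### Over the GO graph

The true path rule closes the per-taxon states over the ontology
(`propagateGO()`): positive states ascend to every `is_a`/`part_of`
ancestor (if a clade performs a specific function it performs the general
one), negative states descend to every descendant (if a general capability
is absent, so is every specialisation). A term reached by both closures in
one taxon becomes ambiguous; frozen seeds win over incoming closure, so a
curated positive survives inside a negative region. `regulates`-type edges
are excluded throughout: the true path rule is asserted over `is_a` and
`part_of` only. Obsolete terms never receive constraints. GO closure runs
after taxonomy propagation.

### Manual constraints and combination

Curated triples (`only_in` / `never_in`) translate into the same
representation: `only_in(g, t)` becomes `in(t, g)` plus `never_in` on every
general taxon disjoint from `t` — neither ancestor nor descendant — in the
reduced tree (`translateOnlyIn()`); at the root nothing is disjoint and no
bans are produced. `combineSets()` merges two constraint sets with a
priority (where both assert different non-neutral states the primary wins
and the conflict is logged), then re-closes over the GO graph.

## Comparison and filtering

`expandFull()` renders a constraint set densely over (general taxa x
non-obsolete terms), applying both states down the taxon subtree, `in` up
the GO ancestors and `never_in` down the GO descendants; `compareSets()`
tallies agreement cell by cell, treating `dubious` as neutral (discordance
means opposite polar claims), and reports fractions over both the dense
space and the union of non-neutral cells, since either denominator is
defensible. `coverageStats()` counts, per namespace, the terms carrying at
least one polar constraint.

For annotation filtering, `transferFromHits()` emulates similarity-based
transfer: per query the best `k` hits (ascending e-value, optionally after
removing a whole clade of subjects to simulate a non-model target), each
subject's terms scored `-log10(evalue)` capped at 180 (e-values below
1e-180, including exact zeros, score 180), non-redundant terms keeping the
maximum. `applyConstraints()` then removes `never_in` terms always and
neutral/dubious terms only under the closed-world option; a back-off flag
replaces a banned term with its nearest non-banned ancestor (breadth-first
up the DAG, ties to the smaller term id) instead of dropping it, default
off. `evaluateGOCentric()` ancestor-closes both predictions and gold
standard before scoring; closure members inherit the maximum score of the
descendants that produced them and are binned by that score. The
alternative — binning a closure member once, globally — is a plausible
reading too; inheritance was chosen because it keeps a term's bin
assignment consistent with the evidence that introduced it, and the
binning happens in one documented place should a user prefer otherwise.

## The synthetic world generator

`generateWorld()` builds a self-contained universe: a three-namespace
layered DAG (roughly 50/30/20 BP/MF/CC, each non-root term with one or two
parents in the layer above, ~15% `part_of` edges), a ranked taxonomy from
at least two superkingdoms down to species, and a ground-truth feasibility
matrix over (general taxa x terms). Infeasibility is planted on whole
(taxonomy-subtree x GO-sub-DAG) blocks — clade-specific loss of a
functional module, the structure the method exploits — which makes the
ground truth true-path-consistent by construction rather than by
post-filtering. `sampleAnnotations()` draws each protein's terms from its
taxon's feasible set, switching to the infeasible set with probability
`noiseRate`; a fraction `experimentalRate` of the *correct* records gets an
experimental code, while noisy records are always IEA, because annotation
errors in real corpora come from electronic transfer, not from curators.
`generateHitTable()` samples subjects from outside the query clade with
log-uniform e-values on [1e-180, 1]. Everything is deterministic given the
seed.

What the generator does **not** emulate: realistic e-value distributions,
sequence similarity structure (hits are random foreign proteins),
annotation-depth bias between well- and poorly-studied species, obsolete
terms and alt_id aliases in the generated ontology, and cross-namespace
`part_of` links. Tests passing on these worlds show the machinery is
correct under the model's own assumptions — clade-structured feasibility,
noise from electronic transfer — not that real GOA meets those assumptions.

## Problem sizes and test design

The test suite verifies the propagation fixed point against randomised
schedules on 500 random trees of up to 50 nodes (20 random orders each),
the cumulative counts against a brute-force closure tally on 200 random
DAGs of up to 40 terms, and true-path consistency of the full pipeline on
100 random worlds. Ground-truth recovery runs on worlds of 60 terms and 30
taxa with 500 proteins per taxon: with clean annotations the seeded cells
must reproduce the planted feasibility exactly (the positive half of that
statement rides on the experimental override, so the recovery worlds use
`experimentalRate = 0.3`, at which a feasible seeded cell without any
experimental record is vanishingly unlikely); with 1% noise, mean accuracy
over ten seeds must stay at or above 95%. The filtering benchmark targets a
leaf of a *robust* clade — the model-organism setting in which constraint
filtering is meaningful; a never-studied clade has no negative constraints
to filter with, which is a feature of open-world reasoning, not a bug. The
acceptance script (`scripts/acceptance.R`) recomputes all of these
quantities from scratch at a fixed seed.

## Known limitations

* Constraints are only as good as the corpus: systematic electronic errors
  that clear the frequency cutoff become positive constraints (the
  experimental override can entrench a single bad curated record), and
  sparse clades yield negatives that really mean "unstudied". The bootstrap
  p-values flag fragile seeds but do not repair them.
* The reduction to class level cannot express within-class variation; a
  function lost in one order of a class is invisible.
* The 75% robustness rule and the polarity thresholds are heuristics;
  they are parameters precisely because no principled value is known.
* Dense expansion materialises a (taxa x terms) matrix and is meant for
  reduced trees of hundreds of taxa, not the full taxonomy.
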
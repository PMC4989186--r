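# taxonConstraints

Taxon constraints for the Gene Ontology, inferred from annotation
frequencies.

GO terms are written to be species-independent, but many functions exist
only in parts of the tree of life — a lysine-synthesis pathway present in
fungi and absent from mammals, photosynthesis absent outside plants and
cyanobacteria. A **taxon constraint** states that a GO term may (`in`) or
may never (`never_in`) annotate gene products of a taxon and its
descendants. Curated constraint lists cover only a small corner of the
ontology; this package infers constraints automatically from a GO
annotation corpus and uses them to strip taxonomically impossible
predictions from automated function-annotation pipelines. It is intended
for computational biologists building or auditing annotation pipelines and
for curators hunting taxon–function inconsistencies.

## The method in brief

1. **Reduce** the NCBI taxonomy to *general taxa* (rank class and above);
   partition them into kingdom-level groups and mark as *robust* those
   whose distinct-GO-term count exceeds 75% of their group reference's.
2. **Count** distinct proteins per (general taxon, term), cumulatively over
   GO descendants, and form the relative probability of association

   $$P_{rel}(t,g) = \frac{c_{t,g}\,/\,{}^{A}c_{t}}{c_{g}\,/\,{}^{A}c}$$

   — the taxon's usage frequency of term *g* over the corpus-wide usage
   frequency in *g*'s sub-ontology *A*.
3. **Polarise**: map `P_rel` into [-1, +1] via `(P_rel − 1)/(P_rel + 1)`;
   high values become positive ("in"), low values negative ("never in").
   A robust taxon with zero occurrences is negative (closed world), a
   non-robust one stays neutral (open world), and any experimentally
   evidenced annotation forces positive.
4. **Propagate**: four local rules extend seed polarities over the reduced
   taxonomic tree (conflicts become `dubious`), then the true path rule
   closes each taxon's states over the GO DAG — positives up to ancestors,
   negatives down to descendants.
5. **Apply**: expanded constraint sets can be compared against curated
   ones, and predictions from similarity-based transfer can be filtered
   under an open- or closed-world reading of "no constraint".

Everything runs on standard formats: OBO ontologies, NCBI taxdump
taxonomies, GAF 2.1/2.2 annotations, GO-consortium constraint triples,
BLAST outfmt-6 hit tables. A synthetic-world generator produces complete
test universes (ontology + taxonomy + ground-truth feasibility +
annotations + hits) in those same formats.

## Worked example

A fully synthetic corpus with known ground truth:

```r
library(taxonConstraints)

world <- generateWorld(nTerms = 60, nTaxa = 30, depth = 5,
                       infeasibleFraction = 0.25, seed = 7)
world
#> SyntheticWorld: 60 terms, 30 taxa, 21 general taxa; infeasible cells: 367 / 1260

gaf <- sampleAnnotations(world, proteinsPerTaxon = 100, noiseRate = 0.02,
                         experimentalRate = 0.2, seed = 8)
ann <- parseGAF(gaf, world@ontology, world@taxonomy)
ann
#> AnnotationSet with 4996 records, 1000 proteins, 10 taxa

cs <- inferConstraints(world@ontology, world@taxonomy, ann,
                       groups = groupSpecFromRanks(world@taxonomy),
                       autoReference = TRUE, cutoff = 100)
cs
#> ConstraintSet with 880 records ( 50 terms x 21 taxa )
#>   states: in=596 never_in=239 neutral=0 dubious=45

coverageStats(cs, world@ontology)
#>            namespace n_terms n_constrained  fraction
#> 1 biological_process      30            30 1.0000000
#> 2 molecular_function      18            17 0.9444444
#> 3 cellular_component      12             3 0.2500000
```

880 sparse records constrain 50 of the 60 terms; every biological-process
term carries at least one polar constraint, while the small
cellular-component namespace is mostly below the frequency cutoff.
Species-level queries resolve through the general-taxon map — here a
species (taxon `25`) of a class (`14`) in which term `GO:0000044` was
planted infeasible:

```r
lookupConstraint(cs, buildGeneralTaxonMap(world@taxonomy), "25", "GO:0000044")
#> [1] "never_in"
```

which matches the planted ground truth
(`world@feasibility["14", "GO:0000044"]` is `FALSE`). The same machinery
reads real data: `parseOBO("go-basic.obo")`,
`parseTaxdump("nodes.dmp", "names.dmp")`,
`parseGAF("goa_uniprot.gaf.gz", ontology, taxonomy)`, then
`inferConstraints(...)` with the shipped kingdom-level `defaultGroupSpec()`.

To filter predictions for a target organism:

```r
preds <- transferFromHits(readHitTable("hits.tsv"), ann, world@taxonomy,
                          k = 100)
kept <- applyConstraints(preds, cs, buildGeneralTaxonMap(world@taxonomy),
                         targetTaxon = "25", world = "open")
attr(kept, "removed")   # what was banned, and why
```

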
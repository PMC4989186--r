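Package: taxonConstraints
Title: Inference and Propagation of GO Taxon Constraints from Annotation Frequencies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers "in taxon" and "never in taxon" constraints between Gene
    Ontology terms and taxa from the frequency of their association in protein
    annotation data, propagates the resulting polarities over a reduced
    taxonomic tree and over the GO graph under the true path rule, and applies
    the constraints to filter taxonomically incompatible predicted
    annotations. Includes readers and writers for OBO ontologies, NCBI taxdump
    taxonomies, GAF annotation files and taxon-constraint tables, tools to
    compare and summarise constraint sets, and a generator of fully synthetic
    benchmark worlds with known ground-truth functional feasibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'constraints-io.R'
    'reduction.R'
    'propagation.R'
    'comparison.R'
    'counts.R'
    'filter.R'
    'gaf.R'
    'inference.R'
    'obo.R'
    'pipeline.R'
    'taxdump.R'
    'synthetic.R'
    'taxonConstraints-package.R'
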
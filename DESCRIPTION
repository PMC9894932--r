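Package: microexposome
Title: Harmonization and Analysis of Gut Microbial Metabolite Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing the gut microbial exposome:
    reading and de-duplicating metabolite registries from tabular files and
    genome-scale metabolic model (GSMM) species lists, canonicalizing chemical
    names with an ordered rewrite-rule table, resolving metabolite identity
    across registries by a hierarchical identifier cascade
    (InChIKey, ChEBI, PubChem, HMDB, BiGG, MetaNetX) with a fuzzy-name
    fallback, summarizing literature-curated evidence of microbial origin
    (faecal in vitro production, reduction under antibiotics, reduction in
    germ-free animals), computing three-set Venn partitions and the predicted
    unique-microbial-metabolite list, and building Tanimoto-thresholded
    chemical similarity networks from SMILES. A seeded synthetic-data
    generator emits linked registries, evidence fixtures and SMILES panels
    with machine-checkable ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    jsonlite,
    yaml,
    ChemmineOB,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
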
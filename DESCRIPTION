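Package: endoprot
Title: Molecular Endotype Discovery from Serum Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for molecular endotyping of inflammatory
    disease cohorts profiled with Olink-style NPX serum proteomics.
    Implements coefficient-of-variation marker QC, k-means endotype
    discovery with perturbation-based stability and resampled
    reproducibility protocols, moderated-t differential expression with a
    three-way Venn grouping of disease signatures, signed weighted
    co-expression network analysis (soft thresholding, topological
    overlap, module eigenproteins, kME hubs, module-trait correlation),
    hub-centred network export, preranked and hypergeometric pathway
    enrichment, and random-forest prediction of endotype membership from
    clinical data. Ships a synthetic-cohort generator with full ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    limma,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
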
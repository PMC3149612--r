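Package: NSAFquant
Title: Spectral-Count Proteomics for Two-Organism Cultures: NSAF
    Normalization, Differential Abundance, Transfer Screening and Gene-Set
    Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Label-free spectral-count quantification for shotgun proteomics
    of mixed two-organism (host/symbiont) cultures. Reads and filters
    peptide-spectrum matches with per-charge XCorr and DeltaCn thresholds,
    assembles proteins under a two-peptide/one-unique rule with target-decoy
    FDR estimation, rebalances shared-peptide spectra proportionally to
    unique evidence, and carries counts through the NSAF, nSpC and RSpC
    normalization chain inside a SummarizedExperiment-derived container.
    Downstream layers provide log2 t-test differential abundance with
    censored fold ratios, an interspecies protein-transfer enrichment factor
    screen, and weighted Kolmogorov-Smirnov gene-set enrichment over
    functional categories and operons. A synthetic-data generator emulates
    the statistical structure of deep MudPIT measurements of an archaeal
    host-symbiont system for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization,
    DifferentialExpression, GeneSetEnrichment, Software
RoxygenNote: 7.3.3
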
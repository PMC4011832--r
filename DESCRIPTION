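Package: orqprofiler
Title: Olfactory Receptor Expression Profiling from TaqMan Array Cq Data
Version: 0.1.0
Authors@R:
    person("ORQ", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantification-cycle (Cq) data from
    custom TaqMan Low Density Arrays profiling the human olfactory
    receptor (OR) gene repertoire in whole olfactory mucosa. Provides
    quality control of RT-minus, genomic-DNA and plasmid calibration
    cards, inter-run calibration, geNorm reference-gene stability
    analysis, two-stage (technical then olfactory-epithelium-specific)
    normalization of relative quantities, copy-number estimation and
    expression-repertoire calling, SAM-style permutation FDR association
    testing against donor covariates, set-level enrichment statistics,
    and a synthetic-cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
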
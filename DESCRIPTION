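Package: ctdnaSieve
Title: Tumor-Informed ctDNA Signal Detection by Multi-Stage Noise Filtering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects circulating tumor DNA (ctDNA) signal in plasma
    whole-genome sequencing using a tumor-informed strategy. Operates on
    forced-call tables of tumor-derived SNVs observed across a patient's
    tumor, matched normal, plasma, a set of control plasmas and a plasma
    pool. Provides basic read-depth/allele-depth/VAF threshold filters, a
    population allele-frequency filter, panel-of-normals construction and
    filtering, and a plasma-pool artefact filter; builds a control-plasma
    noise model and computes signal-to-noise ratios, z-scores and binary
    z-scores with one-sided Student-t significance calls. Includes binomial
    read-thinning to emulate plasma downsampling and a synthetic cohort
    generator with ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, SomaticMutation, VariantDetection, WholeGenome,
    Coverage
RoxygenNote: 7.3.3
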
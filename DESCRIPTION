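Package: gcDormancy
Title: Quantitative Pipelines for Glucocorticoid-Induced Tumor Cell Dormancy
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative procedures
    used to characterise glucocorticoid-induced, p57/CDKN1C-mediated tumor
    cell dormancy: normalised-percentage-inhibition (NPI) scoring of 384-well
    differential-viability drug screens, gene-signature z-score activity
    scoring and cohort stratification, enhancer-accessibility to
    gene-expression linkage against an empirical background-enhancer null,
    region-restricted 4C-seq contact comparison, label-free proteomics
    post-processing with downshifted-normal imputation and IP-enrichment
    calling, and a single-nucleus immunofluorescence quantification pipeline
    (rolling-ball background subtraction, disk median filtering, local mean
    thresholding, distance-transform watershed, control-calibrated marker
    positivity and a protein expression index). Every stage ships with a
    synthetic-data generator with known ground truth so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    EBImage,
    tiff,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'gcDormancy-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'fourc.R'
    'imaging.R'
    'io.R'
    'linkage.R'
    'pipeline.R'
    'proteomics.R'
    'screen.R'
    'signature.R'
    'sim-cohort.R'
    'sim-fourc.R'
    'sim-image.R'
    'sim-lfq.R'
    'sim-plates.R'
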
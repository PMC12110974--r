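Package: DuplexDrops
Title: Duplex Droplet Digital PCR Quantification and Analytical Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for duplex droplet digital PCR (ddPCR) assays that measure a
    rare somatic variant against its wild-type background on two fluorescence
    channels (FAM/VIC). Provides four-cluster droplet classification with
    automatic amplitude thresholding, Poisson single-molecule quantification of
    absolute target concentration and variant allele frequency (VAF) with
    confidence intervals, and the analytical-validation cascade used for such
    assays: linearity against gravimetric mixtures, repeatability (RSD),
    non-parametric limit of blank (LOB), probit-regression limit of detection
    (LOD95), and Total-Error limit of quantification (LOQ). Includes fragment-
    size and spectrophotometric purity checks for ctDNA-mimicking reference
    materials, and a droplet-level simulator of duplex wells, blank panels,
    gravimetric dilution series, and mono-nucleosome fragment profiles so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
biocViews: ddPCR, Software, QualityControl, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
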
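Package: mrdppm
Title: Tumor-Informed ctDNA Detection at Parts-per-Million Tumor Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tumor-informed minimal residual disease (MRD) pipeline for
    ultrasensitive circulating tumor DNA (ctDNA) detection from plasma
    whole-genome-informed bespoke panels. Designs patient-specific panels of
    up to ~1,800 somatic SNV targets ranked by signal-to-noise (tumor allele
    frequency over a 12-class substitution background error rate estimated
    from healthy plasma), plus 43 population SNVs for quality assurance.
    Suppresses sequencing noise by positional duplex molecular consensus
    (read-pair grouping, allele-based group splitting, quality and agreement
    masking, strand confirmation), aggregates alt-supporting unique molecules
    across the panel, and calls detection with a one-tailed Poisson test
    against the accumulated background noise, reporting tumor fraction in
    parts per million (ppm) of unique molecules. Includes an analytic and
    Monte-Carlo 95% limit-of-detection predictor, cohort stratification by
    the detected-median ctDNA level, and a synthetic cfDNA simulator (duplex
    read families, substitution error model, Poisson molecule yields,
    ppm-scale spike-ins) so specificity, LOD, and tumor-fraction recovery are
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
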
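Package: twasvc
Title: Variance Control for Polygenicity-Driven Inflation in TWAS and xWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide association studies (TWAS) and related xWAS
    methods test the association between a genetically predicted molecular
    mediator and a target complex trait. When the target trait is highly
    polygenic, the standard correlation-based Z statistic is inflated, with
    E[Z^2] growing linearly in the product of GWAS sample size and trait
    heritability. This package simulates polygenic null and alternative
    target traits against predicted mediators, estimates the per-mediator
    inflation slope Phi by regressing mean Z^2 on N*h2, and applies the
    variance-control correction Z/sqrt(1 + Phi*N*h2) to produce calibrated
    association statistics, alongside a genomic-control baseline and
    calibration/power diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
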
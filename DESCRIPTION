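Package: dkoscreen
Title: Simulation and Analysis of Asymmetric Double-Knockout CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for pooled double-knockout CRISPR screens with an
    asymmetric dual-guide library design, as used to map genetic interactions that
    modulate cancer-cell resistance to T cell killing. Builds combinatorial
    dual-guide libraries (double knockouts crossed with single-knockout and
    double non-targeting controls), simulates the full screen (plasmid pool,
    low-MOI transduction bottleneck, effector-to-target-ratio-scaled immune
    selection, overdispersed sequencing) with known ground truth, counts paired
    guide cassettes from paired-end reads, normalizes and quality-controls count
    matrices, scores enrichment with an empirical false-discovery rate estimated
    from non-targeting controls, and calls additive or subtractive genetic
    interactions via externally studentized residuals from an
    observed-versus-expected regression with a Bonferroni outlier test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
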
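Package: apmspi
Title: Differential Interactome Analysis for AP-MS Pull-Downs with Bait
    Regression and Pi-Value Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed affinity-purification
    mass-spectrometry (AP-MS) experiments that compare the interactomes of
    several bait protein variants against an empty-vector control. Protein
    abundances are log2-transformed and centered to the row mean within each
    replicate batch; candidate binders are called by two-sample t-tests
    against the control at fold-change and p-value thresholds and partitioned
    across variants; variability in the amount of immunoprecipitated bait is
    removed by regressing every prey profile on the bait profile and keeping
    the residuals; preys are filtered by positive Pearson correlation to the
    bait; variant-versus-variant differences are scored by matched per-batch
    log2 ratios, one-sample t-tests, and pi values (log2 fold change times
    -log10 p) used for significance ranking; ranked selections are tested for
    gene-set overrepresentation by the hypergeometric distribution. A
    synthetic-data generator with planted ground truth supports end-to-end
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
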
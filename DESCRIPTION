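Package: senescreen
Title: Analysis of High-Throughput Telomere-Initiated Senescence Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of genome-wide,
    serially-passaged senescence screens in budding yeast. Culture-size
    tables produced by plate image quantification are variance-stabilised
    with a power transform, summarised into per-genotype mean density
    profiles (MDPs), and classified by Pearson-correlation similarity to
    three archetypal senescence trajectories (normal senescence,
    accelerated entry with no recovery, and accelerated entry with fast
    recovery). The package also computes recovered-fraction statistics,
    quality-threshold (QT) clustering of profiles, gene-set overlap and
    genetic-interaction quadrant summaries, and ships a seeded stochastic
    simulator of senescence screens with known ground-truth class labels
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
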
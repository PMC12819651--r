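Package: herbfront
Title: Pareto-Front Mining of Historical Recipe Corpora and Nuclear
    Receptor Coregulator Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage candidate-discovery pipeline for botanical drug
    screening. Stage one mines a corpus of historical medical recipes:
    recipes are linked to indication search terms, per-drug frequency and
    corpus-relative frequency are computed, an occurrence threshold is
    applied, and iterative Pareto-front (non-dominated sorting) ranks
    identify drugs that balance overall frequency with indication
    specificity, aggregated across indication subsets. Stage two analyses
    nuclear-receptor coregulator-binding plates: fluorescence signals for
    101 coregulator motifs are normalised to the unstimulated (Apo)
    receptor as log2 fold changes, motifs are classified as
    glucocorticoid-responsive or plant-exclusive, bell-shaped active
    fraction clusters are detected along the 96-fraction separation
    sequence, apex fractions are statistically confirmed, and competition
    (motif-spiking) experiments are summarised as inhibition calls.
    Seeded synthetic-data generators emulate both data sources so every
    stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
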
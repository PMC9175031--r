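Package: rivalryr
Title: Perceptual Grouping During Binocular Rivalry: Response-Log Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for dual-button dichoptic response logs from
    perceptual-grouping binocular-rivalry experiments. Converts two-channel
    button-press interval logs into exhaustively labelled percept timelines
    (grouped, ungrouped, mixed, transition), with transition-wave overlaps
    excluded from dominance-epoch calculations; computes dominance times,
    rivalry rates (switches per minute), mean dominance epochs and
    between/within-hemifield epoch differences; and runs the accompanying
    statistical battery (mixed factorial ANOVA with Type III sums of squares,
    Greenhouse-Geisser correction, partial eta-squared, pairwise comparisons,
    t-tests with Cohen's d, Mann-Whitney U, correlations). A seeded
    synthetic-observer simulator generates cohorts of button logs from a
    coupled two-zone rivalry renewal process plus a motor layer, so the whole
    pipeline is exercisable end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
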
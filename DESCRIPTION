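Package: hydratox
Title: Whole-Organism Nanotoxicity Bioassays in Hydra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for acute and sublethal toxicity bioassays in
    the freshwater polyp Hydra vulgaris. Summarises ordinal morphology
    (Wilby) scores over dose and time, derives quantal mortality tables from
    a death threshold, estimates median lethal concentration (LC50) and
    median lethal time (LT50) by the trimmed Spearman-Karber method with
    pool-adjacent-violators monotone smoothing and delta-method confidence
    intervals, computes the tentacle regeneration index (TRI) over a 14-day
    regeneration window, and fits exponential population growth to obtain
    growth constants and doubling times with slope-equality tests. A
    synthetic bioassay generator with known ground truth (dose-dependent
    log-logistic lifetimes, ordinal score decay, tentacle emergence and
    elongation, budding growth) supports parameter-recovery testing and
    end-to-end demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
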
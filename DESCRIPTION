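Package: basingauge
Title: Attraction Basins as Robustness Gauges for Threshold Boolean
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive attractor and attraction-basin analysis of threshold
    Boolean automata networks under block-sequential update schedules, with
    boundary-node clamping, basin size and modified-Hausdorff distance
    metrics, and exact characteristic polynomials of basin-to-basin passage
    probabilities under independent bit-flip perturbation.  Ships the
    Mendoza & Alvarez-Buylla floral-morphogenesis network of Arabidopsis
    thaliana together with a gibberellin-sensitive extension (the rga
    boundary gene) and a scripted comparison of the two hormone regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
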
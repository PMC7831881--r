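Package: pauseflow
Title: Cardiorespiratory Pausing Analysis for Flow-Through Respirometry
    and Photoplethysmography in Decapod Crustaceans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify episodic metabolic pausing behaviour in
    decapod crustaceans under warming and elevated seawater CO2. Includes
    a seeded generator of synthetic cardiorespiratory recordings (episodic
    oxygen-consumption cycles, paired optode traces through a mixed
    flow-through chamber, infra-red photoplethysmography pulse trains, and
    vessel flow-velocity records), flow-through respirometry metabolic-rate
    computation with inlet-outlet delay correction, PPG beat detection with
    per-minute heart rate, stroke-volume proxy and cardiac output,
    quartile-occupancy pausing statistics with robust outlier screening,
    a seawater carbonate-system solver for the (pCO2, pH) input pair, and
    a repeated-measures inference layer (mixed models with animal random
    intercepts, Tukey HSD, Kruskal-Wallis with Tamhane T2, Wilcoxon
    rank-sum).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
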
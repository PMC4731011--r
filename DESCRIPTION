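Package: rateshift
Title: Rate-Ratio Change-Point Analysis for Paired mRNA/Protein Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves paired mRNA and protein expression time courses into
    RNA-level and protein-level regulation. Models the log ratio of synthesis
    to degradation rates as piecewise constant between sampling times, scores
    each interior time point with a Bayesian change-point probability (CPS),
    and thresholds calls by a direct posterior false discovery rate. Includes
    the accompanying preprocessing (quantile and LFQ-sum normalization,
    jackknife total-range-of-variation spike filtering, lowess smoothing,
    replicate consistency), phase summaries and discordance/buffering
    detection, profile clustering, and paired kinetic simulators with known
    ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
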
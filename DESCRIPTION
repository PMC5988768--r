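Package: psoct
Title: Simulated Polarisation-Sensitive OCT of Indented Cartilage and
    Birefringence-Coefficient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jones-calculus simulator for two-channel polarisation-sensitive
    optical coherence tomography (PS-OCT) B-scans of mechanically indented
    articular cartilage, together with the phase-retardation processing
    pipeline that quantifies tissue birefringence as a retardation gradient
    (birefringence coefficient, rad/mm): surface detection, maximum-depth
    thresholding, A-scan window averaging, running-average smoothing, and the
    cumulative absolute phase change per unit tissue depth. Includes grade
    presets for healthy and early-degenerate cartilage, a virtual Berek
    compensator experiment for phase-measurement validation, and one-way
    ANOVA with Tukey post-hoc comparisons across degeneration grades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
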
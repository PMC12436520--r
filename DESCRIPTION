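Package: algastress
Title: Single-Cell Motility, Growth Kinetics and Chlorophyll Response of
    Microalgae Under Silver Ion Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify the biophysical response of Chlamydomonas
    reinhardtii microalgae to silver (Ag+) ion exposure. Implements
    single-particle detection (multi-scale Laplacian-of-Gaussian blob
    detection) and trajectory linking with bounded search radius and gap
    memory, per-step speed and turning-angle statistics with replicate-level
    summaries and drift diagnostics, Gompertz growth-curve fitting with lag
    time, maximum growth rate and asymptote extraction plus hormesis
    comparison across conditions, and spectrophotometric chlorophyll a/b
    quantification from absorbance triplets. A synthetic-data module
    generates ground-truth swimmers, rendered videos, replicated growth
    curves and absorbance triplets with the statistical structure the
    analyses assume, so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
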
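Package: dwmrs
Title: Simulation and Analysis of Diffusion-Weighted MR Spectroscopy Metabolite Decays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diffusion-weighted magnetic resonance spectroscopy (dMRS)
    of brain metabolites: simulation of shot-level diffusion-weighted spectra
    with known ground truth, shot-level phase/frequency drift correction and
    outlier rejection, linear-combination spectral quantification with
    Cramer-Rao lower bound (CRLB) filtering, fitting of the randomly-oriented
    sticks (powder-average) model and the second-order cumulant (kurtosis)
    expansion to metabolite signal decays with the error-function radius of
    convergence cutoff, and paired-cohort statistics (repeated-measures
    two-way ANOVA with Bonferroni post-hoc tests). Designed around tidy
    tables so each stage's output pipes into the next.
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
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
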
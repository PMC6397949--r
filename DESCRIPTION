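Package: blinksync
Title: Dyadic Eye-Blink Coupling and Interbrain Synchronization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dyadic (hyperscanning) eye-contact
    experiments. Extracts eye-blink motion-energy time series from eye-region
    video frames, detects blink events, quantifies directional behavioral
    coupling between partners with the Akaike noise contribution ratio (NCR)
    derived from bivariate autoregressive models with AIC order selection,
    runs the repeated-measures inferential layer (generalized eta-squared
    ANOVA, Bonferroni-corrected paired t tests, pairwise confidence
    intervals, 2-SD outlier screening), and computes homologous-voxel
    interbrain synchronization maps (GLM task residualization, condition
    concatenation, Pearson correlation with Fisher r-to-z). A synthetic dyad
    generator with known ground-truth coupling drives every stage, so the
    full pipeline is testable without access to recorded data.
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
    utils
Suggests:
    png,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
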
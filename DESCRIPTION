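Package: haaquant
Title: Quantitative CT Detection of Interstitial Lung Abnormalities by
    High Attenuation Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative chest-CT lung densitometry and its
    evaluation as a screen for interstitial lung abnormalities (ILA).
    Computes the percentage of lung occupied by high attenuation areas
    (HAA, -600 to -250 Hounsfield Units), LAA-950 percent emphysema and
    CT-derived total lung capacity from calibrated HU volumes; generates
    synthetic chest phantoms with known ground-truth composition for
    validating the densitometry; simulates subject cohorts with
    configurable logistic (visual ILA status), linear (TLC) and additive
    genetic structure; and provides agreement statistics (Cohen's kappa,
    sensitivity/specificity/PPV/NPV, c-statistic, threshold sweeps) and
    regression-based association analyses (odds of ILA per 1% HAA, TLC
    slope, effect modification, single-variant additive genetic models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
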
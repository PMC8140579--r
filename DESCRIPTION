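Package: cryoleak
Title: Cold Hardiness from Electrolyte-Leakage Freeze-Thaw Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plant cold hardiness from electrolyte-leakage
    freeze-thaw experiments on woody tissue. Converts raw conductivities to
    relative leakage (R), index of injury (I) and adjusted index (I_adj);
    fits constrained four-parameter log-logistic and Gompertz damage curves
    per genotype or species and extracts critical temperatures (LT20/LT50/
    LT80, LTmax); calibrates liquid-nitrogen against autoclave maximum-damage
    controls with zero-intercept Deming (errors-in-variables) regression;
    cross-validates leakage against visual damage scores (threshold grids of
    correlation, bias and RMSE; lowest survival temperature) and against
    differential thermal analysis via algorithmic low-temperature exotherm
    detection; and simulates complete experiments with known ground truth.
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
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
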
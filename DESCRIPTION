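Package: uvcdose
Title: Dose Equivalence and Germicidal-Effect Analysis for Continuous
    and Pulsed UV-C LED Disinfection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Plans energy-equivalent UV-C LED treatments in continuous
    light and two pulsed-light modes (power-pulsed and time-pulsed),
    renders the corresponding irradiance pulse trains and integrates
    their fluence, computes germicidal effect (log reduction values) and
    effective germicidal effect profiles from plate-count data, accounts
    for electrical energy consumption, and runs the standard
    Shapiro-Wilk / one-way ANOVA / Tukey comparison with compact letter
    displays. Includes a synthetic plate-count generator emulating a
    completely randomized fresh-produce disinfection experiment so the
    whole pipeline is testable without wet-lab data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
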
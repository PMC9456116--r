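Package: amglass
Title: Glass-Transition Dynamics and Physical Stability of Amorphous Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the glass transition, molecular dynamics, and
    physical stability of amorphous pharmaceuticals and drug-excipient
    mixtures. Fits Havriliak-Negami relaxation functions (with a
    dc-conductivity term) to broadband dielectric spectra, parametrizes
    relaxation maps with the Vogel-Fulcher-Tammann equation to obtain the
    dielectric glass-transition temperature, isobaric fragility and windowed
    Arrhenius activation energies, detects isothermal crystallization onsets
    in refractometry time traces and fits the Arrhenius nucleation law,
    computes the dynamics-crystallization coupling parameter, and predicts
    mixture glass-transition temperatures with the Couchman-Karasz equation.
    A synthetic-data generator emulates every instrument modality with known
    ground truth so the full analysis chain is testable without instruments.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
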
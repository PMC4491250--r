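Package: twinstandards
Title: Adjustable Fetal Weight Standards for Twin Pregnancies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs population-adjustable fetal weight standards for twins
    by rescaling the Hadlock median fetal growth curve with a proportionality
    ratio anchored at a population's mean birthweight at 37 completed weeks.
    Provides percentile curves, z-scores and SGA/AGA/LGA classification under
    a constant coefficient-of-variation normal model; registry-processing
    utilities (LMP/clinical-estimate gestational-age reconciliation, low-risk
    cohort filtering, anchor estimation by race/ethnicity); empirical weekly
    percentile curves and quantitative curve comparison; and a seedable
    synthetic twin-birth registry generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
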
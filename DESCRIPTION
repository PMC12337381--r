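Package: isocontam
Title: Quantifying Carbon-Isotopic Contamination in Dual-Chamber 13CO2/12CO2 Labelling Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing carbon-isotopic contamination in paired-chamber
    13CO2/12CO2 labelling experiments. Implements delta-notation arithmetic and
    the Farquhar source-tissue discrimination relations, open-system chamber CO2
    and 13C mass balances (pure outlet delta13C after Evans, contamination-free
    reference delta13C, respired delta13C, canopy exchange rates), the paired-chamber
    contamination-fraction statistic with sensitivity and error-propagation analyses,
    quality-control filtering of chamber time series (photoperiod-start, door-opening
    and interquartile-range rules), carbon-mass bookkeeping for water-soluble
    carbohydrate fractions, and a virtual two-chamber experiment simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
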
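Package: hescore
Title: Humane-Endpoint Scoring and Welfare Monitoring for Rodent
    Carcinogenesis Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for humane-endpoint (HE) assessment in chemically induced
    colorectal-carcinogenesis trials in rats: a declarative 14-parameter
    welfare score sheet with per-parameter euthanasia triggers and a total
    critical limit, a refined sheet adding abdominal thermography, priapism
    and sudden body-weight gain, body-weight and consumption metrics
    (signed weekly ponderal gain), a prodrome early-warning detector for the
    stereotyped pre-death sign sequence, Kaplan-Meier survival with
    administrative censoring at scheduled sacrifice, group score and
    temperature statistics with post hoc comparisons, and a seeded
    longitudinal cohort simulator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    survival,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
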
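Package: oralproj
Title: Multi-State Population Projection of Dental Caries and Periodontal
    Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cohort-component, multi-state (stock-and-flow) population
    model projecting the adult population in each oral-health state: a
    three-state dental caries chain (no caries, untreated caries, treated
    caries), a four-state periodontal pocketing chain (thresholds 4, 6 and
    9 mm) and a four-state loss-of-attachment chain for ages 55 and over.
    Includes the demographic engine (births, life-table mortality, net
    migration, annual aging with an open 100+ cohort), initialization from
    age-band prevalence tables, calibration of age-constant transition
    rates against prevalence-derived target series, Monte-Carlo sensitivity
    envelopes under simultaneous parameter variation, age-band report
    tables, and a synthetic-data generator with known ground-truth rates
    for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
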
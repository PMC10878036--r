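Package: lakevirome
Title: Seasonal Virus-Host Dynamics in a Stratified Lake from Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream inference for a year-long, two-depth freshwater
    virome and 16S time series: season classification from temperature
    profiles, coverage-gated TPM for viral contigs, habitat-preference
    statistics, Bray-Curtis time-lag community turnover, dominance-pattern
    classification, prioritized multi-evidence phage host assignment, and
    extraction of virus-prokaryote infection pairs by correlation with
    false-discovery-rate control. Includes a seeded synthetic-lake
    generator with ground truth so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
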
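Package: udise
Title: Universal Drug-Induced Sedation Endoscopy (uDISE) Scoring and
    Classification Crosswalks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the uDISE model for recording drug-induced sedation
    endoscopy (DISE) findings: a controlled vocabulary of seven upper-airway
    sites (nose, velum, tonsils, oropharynx/lateral pharyngeal wall, tongue
    base, epiglottis, larynx), three obstruction degrees, three collapse
    configurations, a compact score-string notation and an additive severity
    index. Ships a declarative, direction-specific rule base that converts
    findings between uDISE and four established DISE classification systems
    (Pringle/Croft grading, VOTE, NOHL and P-T-L-Tb-E), tracking ambiguity,
    lossiness and rule provenance, regenerating the reference crosswalk grid,
    summarising cohorts, and simulating seeded synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'vocabulary.R'
    'AllClasses.R'
    'AllGenerics.R'
    'finding.R'
    'profile.R'
    'notation.R'
    'io.R'
    'rules.R'
    'engine.R'
    'reporting.R'
    'simulate.R'
    'cli.R'
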
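Package: addiscore
Title: Scoring and Psychometric Validation of the Autoinflammatory Disease Damage Index
Version: 1.0.0
Authors@R: person("ADDI", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An executable implementation of the Autoinflammatory Disease
    Damage Index (ADDI), the damage instrument for the four main monogenic
    autoinflammatory diseases (FMF, CAPS, TRAPS and MKD): glossary-faithful
    grading of clinical evidence into item points, damage-eligibility
    filtering, category capping and total score computation. Ships the
    psychometric machinery used to validate such instruments under an
    observer-nested-within-subject design: one-way random-effects intraclass
    correlation with F-based confidence intervals for unbalanced groups,
    Cronbach's alpha with interitem redundancy screening, and Spearman rank
    correlation with Fisher or bootstrap confidence intervals. A synthetic
    study simulator generates complete grouped-rater validation studies with
    controlled item prevalence and tunable rater reliability, so every
    estimator is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
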
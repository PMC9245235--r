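Package: pharmsched
Title: Pharmacotherapy Review Alerts and Genetic-Algorithm Medication Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Clinical decision support for pharmacotherapy review. Crosses a
    structured drug knowledge base (active principles, dose limits,
    contraindications, and typed no-use / scheduling / observation interaction
    rules) against a patient profile to emit safety alerts (contraindication,
    drug-drug interaction, therapeutic duplication, over- and underdose, food
    relations), and assigns clock times to every prescribed dose with a
    seeded genetic algorithm that minimises penalties for routine, spacing,
    interaction-interval and food-timing violations.  Ships ten hypothetical
    planted-error cases as executable fixtures, a synthetic case generator, a
    10-item pharmacotherapy review scoring instrument (IARF), and weighted
    Cohen's kappa with asymptotic and bootstrap confidence intervals for
    ordinal rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
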
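Package: factsaudit
Title: Scoring and Reliability Assessment for the FACTS Route Audit Instrument
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Machine-readable definition of the Field Audit for Children's
    Active Transport to School (FACTS) instrument, its hierarchical 0-1
    scoring protocol (item, domain, segment/crossing, route, school), and a
    complete inter- and intra-rater reliability suite: percentage agreement,
    Cohen's kappa, linearly weighted kappa, and two-way random-effects
    intraclass correlation with F-based confidence intervals, interpreted on
    the Landis-Koch scale. Includes a latent-category paired-audit simulator
    with analytic expected-agreement oracles so every statistic can be
    exercised without field data, plus publication-style item and score
    reliability reports and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
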
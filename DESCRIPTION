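Package: ppv23cba
Title: Decision Tree-Markov Cohort Cost-Benefit Model for PPV23
    Vaccination in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort state-transition (Markov) model and cost-benefit
    accounting for evaluating free versus self-paid single-dose 23-valent
    pneumococcal polysaccharide vaccine (PPV23) programmes in adults aged
    60 and over. Builds arm-specific annual transition matrices over five
    health states, runs a closed cohort over a multi-year horizon,
    computes discounted benefits (averted hospitalization and caregiver
    costs), programme costs, net benefit, benefit-cost ratio and ICER,
    and performs one-way (tornado) sensitivity analysis over parameter
    ranges. Ships a base-case configuration, a seeded scenario generator
    for testing, and CSV/JSON report writers with a thin command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
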
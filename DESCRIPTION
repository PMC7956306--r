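Package: ltcfactor
Title: Cost-Free Conversion of Retirement Pensions into Long-Term-Care Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Actuarial toolkit for converting a defined-benefit retirement
    pension into a long-term-care (LTC) support benefit at no added cost to
    the scheme. Builds and validates cohort life tables by sex and health
    state, transforms general mortality schedules into severely-dependent
    schedules via multiplicative, additive and mixed logistic excess-mortality
    corrections (with least-squares parameter fitting), computes the age- and
    sex-specific conversion factor lambda as the ratio of independent to
    dependent life expectancy, projects cohorts through a discrete annual
    multistate model (active/retired/dependent/disabled/dead), and verifies
    the cost-free equivalence between the retirement annuity and the
    converted LTC benefit via actuarial present values. Ships synthetic
    Gompertz-Makeham generators and the printed 1970-cohort Spanish fixture
    so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
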
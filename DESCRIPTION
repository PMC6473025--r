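Package: maxspan
Title: Maximal-Lifespan Estimation Under Gompertz Mortality with Cohort
    Simulation and Donor-Chimerism Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for rodent lifespan-extension studies:
    parametric survival modelling under the Gompertz mortality law
    (survival function, hazard, quantiles, least-squares fitting, exact
    inverse-CDF sampling), three maximal-lifespan (MLS) estimators (direct
    top-decile mean, model-based tail conditional expectation, and their
    uncertainty-weighted combination), lifespan-extension statistics, and a
    correction converting observed GFP-positive bone-marrow cell fractions
    into donor chimerism for heterozygous donors.  A synthetic-study
    generator emulates the full design of a late-life bone-marrow
    transplantation experiment (pre- and post-intervention mortality,
    per-injection embolic risk, scheduled sacrifices, per-image binomial
    GFP counts) so that every pipeline stage is testable without raw
    animal data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
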
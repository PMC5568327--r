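Package: cessnet
Title: Dynamic Social Network Analysis for Online Smoking-Cessation Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct directed reading-tie networks from
    time-stamped clickstream logs of an online smoking-cessation community,
    and to relate network dynamics to 30-day abstinence. Implements
    sessionization of page views under a 30-minute inactivity rule,
    clickstream-based tie formation (a tie points from a content author to
    each member who read that content), the awareness-conditioned
    out-degree centrality (readers who responded in-thread and whose
    response the author subsequently viewed), cumulative weekly centrality
    trajectories, engagement-based stratification of participants into
    non-users, passive users and active users, and group-specific logistic
    abstinence models with sandwich (robust) standard errors, square-root
    scale network predictors, quartile-scaled covariates, stepwise
    reference-model selection and cross-validated AUC. A synthetic
    clickstream and cohort generator with planted outcome effects makes the
    whole pipeline testable without access to any platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    graphics,
    igraph,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
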
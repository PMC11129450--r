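Package: pgxtraj
Title: Pharmacogenomic Metabolizer Status and Antidepressant Treatment
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how CYP2D6 and CYP2C19 metabolizer status
    relates to long-term antidepressant use in observational cohorts.
    Translates star-allele diplotypes to metabolizer phenotypes under DPWG
    or CPIC conventions, classifies antidepressants by ATC code as CYP2D6
    and/or CYP2C19 substrates, labels longitudinal medication-use
    trajectories (maintained, switched, discontinued) across an 11-period
    observation window, aggregates 12-item side-effect checklist responses
    into serotonergic, cholinergic and histaminergic counts, and provides
    the statistical layer used for such analyses: crude odds ratios with
    Wald intervals, logistic regression by iteratively reweighted least
    squares, tie-corrected Mann-Whitney U tests with an exact-enumeration
    mode, and post-hoc two-proportion power via Cohen's h. A synthetic
    cohort generator with Hardy-Weinberg diplotype sampling and injectable
    effect sizes supports end-to-end testing when the underlying clinical
    data are access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
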
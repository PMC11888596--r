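Package: orgaging
Title: Multi-Organ Biological Aging and Healthy Lifestyle Change Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how short-term lifestyle change relates to
    comprehensive and organ-specific biological aging in two-wave cohort
    data. Implements sex-stratified Klemera-Doubal biological age estimation
    from routine clinical biomarkers for a comprehensive panel and five
    organ-system panels (cardiopulmonary, metabolic, liver, renal, immune);
    a five-factor Healthy Lifestyle Index with a modified alternate
    Mediterranean diet score; disease-based validation of the biological
    ages via logistic regression; two-wave fixed-effects (first-difference)
    estimation of lifestyle-change effects on biological age acceleration
    with subgroup heterogeneity Q tests and sensitivity variants; and
    quantile G-computation of the joint lifestyle mixture effect with
    sign-grouped relative-contribution weights. A seeded synthetic cohort
    generator with known ground truth supports parameter-recovery testing
    of every stage without access to restricted cohort microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
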
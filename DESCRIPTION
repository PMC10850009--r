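Package: certifyr
Title: Statistical Certification and Post-Certification Monitoring of
    Reference Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical evaluation of reference material
    production data: homogeneity studies by one-way nested ANOVA with
    between-bottle uncertainty, classical and Arrhenius (accelerated)
    stability studies with prospective shelf-life estimation,
    interlaboratory certification studies with a battery of normality,
    variance-homogeneity, compatibility and outlier tests (Grubbs, Dixon,
    Cochran, Bartlett, Scheffe) with sequential user-driven exclusion,
    assembly of GUM-style uncertainty budgets with DIN 1333 rounding, and
    post-certification monitoring via a stability criterion and long-term
    stability regression. Includes spreadsheet template readers, a
    versioned JSON session container, a synthetic fixture generator with
    known ground truth, and HTML reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
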
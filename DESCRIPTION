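Package: pedri
Title: Indirect Age- and Sex-Specific Pediatric Reference Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Establishes age- and sex-specific pediatric reference
    intervals from routine laboratory data by the indirect method:
    iterated Tukey outlier removal per age-sex cell, decision-tree
    proposal of age cut points, Harris-Boyd and Lahti validation of
    adjacent subgroups with a merge/re-split refinement loop, and a
    grid-searched inverse Box-Cox estimator of the non-pathological
    central distribution with percentile-bootstrap confidence
    intervals. Ships a synthetic-cohort generator for blood trace
    elements (Cu, Zn, Ca, Mg, Fe, Pb) whose closed-form generating
    quantiles serve as a recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
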
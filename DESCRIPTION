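Package: hcindex
Title: Hip Congruency Index Morphometry for Canine Hip Dysplasia Screening
Version: 0.1.0
Authors@R:
    person("HCI", "Maintainers", email = "maintainers@hcindex.org",
           role = c("aut", "cre"))
Description: Tools to quantify radiographic hip congruency in dogs from
    polygonal annotations of ventrodorsal hip-extended radiographs. The
    Hip Congruency Index (HCI) is the fraction of the projected
    acetabular coverage area occupied by the femoral head, computed by
    general simple-polygon intersection of annotation outlines; the
    Norberg angle is measured from point landmarks. Includes readers and
    writers for LabelMe-style annotation JSON and flat measurement
    tables, a synthetic hip generator with known ground truth spanning
    FCI-like congruency grades, the agreement and reliability battery
    used to validate observer-based measurements (paired t-test,
    Bland-Altman limits of agreement, intraclass correlation ICC(3,1)),
    and unequal-variance group comparison (Welch's ANOVA with
    Games-Howell post hoc) across hip dysplasia grades.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
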
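Package: mtxresponse
Title: Dose-Normalized Methotrexate Response Analysis for Rheumatoid
    Arthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the DAS28-CRP composite disease-activity score from its
    components, the trapezoidal area under longitudinal DAS28 trajectories,
    the "improved DAS28 area" relative to a sustained-maximal-disease
    reference, and the dose-normalized treatment-response statistic index R
    (improved area per milligram of cumulative methotrexate) over 0-3 and
    0-6 month windows.  Classifies disease-control status over months 6-12,
    maps folate-pathway SNP genotype calls (RFC1, FPGS, GGH, MTHFR, TYMS) to
    binary carrier groups, and compares groups with exact or approximate
    Mann-Whitney U tests with tie handling.  Includes a synthetic cohort
    generator emulating a 21-patient retrospective study design, and a
    one-command pipeline that writes the full comparison report bundle with
    a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
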
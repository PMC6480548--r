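Package: rems
Title: Routine Efficiency Monitoring for Health Facility Expenditure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes quarterly unit expenditure per health service at the
    facility level by linking a hierarchical expenditure ledger to routine
    service-output counts. Expenditures recorded against hierarchical account
    codes at national, provincial or district level are isolated to the
    programme of interest with elicited HIV-share weights, stepped down to
    facilities through flow-down rules (retaining above-facility expenses at
    each level), distributed across service and resource-category cells with a
    per-facility resource allocation matrix built from ingredients-based
    facility assessments, and divided by same-quarter output volumes. Includes
    roll-ups, robust outlier flagging, trend and cost-volume views,
    data-quality reporting, a synthetic-data generator with known ground truth
    for end-to-end parameter recovery, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
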
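Package: cdrscore
Title: Scoring the Quality of Epidemic Data Reporting with the CDRS Rubric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the COVID-19 Data Reporting Score (CDRS), a
    semi-quantitative rubric for assessing the quality of public-health
    data reporting across jurisdictions. The rubric spans four categories
    (availability, accessibility, granularity, privacy) over five report
    items (confirmed, deaths, recovered, quarantine, ICU), for 45
    indicators in total. The package declares the rubric as data, reads
    and validates per-state scoring sheets, computes NA-adjusted
    normalized category scores and the overall CDRS, summarizes scored
    cohorts (five-number summary, rankings, per-indicator reporting
    counts), correlates scores against an external development index,
    and generates synthetic cohorts with planted quality structure so
    the whole pipeline can be exercised without any curated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
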
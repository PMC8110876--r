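Package: vaxwatch
Title: Rule-Based Surveillance of Vaccine-Opposition Discourse on Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infodemiological surveillance of vaccine-opposition
    conversations on microblogging platforms. Implements a boolean keyword
    query dialect (standalone terms, concurrent anchor/context term pairs,
    exclusion terms, hashtag variants), precision-validated rule-based
    multi-label theme and misinformation tagging, engagement-based monthly
    top-author identification, and chi-squared comparison of theme
    proportions between influential and general opposition authors. A
    synthetic corpus generator with full ground truth supports end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
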
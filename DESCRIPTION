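Package: trialwaste
Title: Auditing Outcome-Related Research Waste in Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing why randomized controlled trials fail to
    contribute to the meta-analyses of the important outcomes of systematic
    reviews. Builds trial-by-outcome contribution matrices from a review
    corpus, classifies each missing (trial, outcome) pair as inadequate
    planning, selective reporting, incomplete reporting, indistinguishable,
    or another situation, and assesses how much of the resulting research
    waste was avoidable given expert feasibility, cost, and importance
    judgments. Includes a canonical corpus interchange format (JSON and a
    tidy CSV bundle), a reader for a RevMan 5 review-XML subset, a
    deterministic fixture builder that materializes a corpus from printed
    marginal counts, descriptive summaries with binomial confidence
    intervals, and a synthetic review-corpus generator for testing the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
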
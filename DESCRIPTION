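Package: credalpod
Title: Credal Networks and Naive Bayes Classification for
    Place-of-Death Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring determinants of cancer patients' place
    of death with discrete credal networks built from expert-elicited
    probability intervals and qualitative judgments.  Provides
    credal-set geometry (coherence checking, interval tightening,
    vertex enumeration), exact and approximate lower/upper posterior
    inference under the strong extension, interventional queries by
    graph mutilation, a lower-bound impact statistic, a naive Bayes
    place-of-death classifier tolerant of missing categorical data,
    and a synthetic cohort generator that reproduces published
    marginal summaries exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
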
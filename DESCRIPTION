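Package: vapemine
Title: Aspect-Based Sentiment Opinion Summarization for E-Liquid Review Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining rated product-review corpora of e-liquids
    (electronic nicotine delivery system refills). Discretizes overall and
    aspect ratings into three-valued sentiment labels, ranks the four rated
    aspects (flavor accuracy, value, cloud production, throat hit) by a
    normalized total-information-gain importance statistic computed from an
    ID3 decision tree, extracts aspect-sentiment opinion pairs from review
    text via adjectival-modifier and copular dependency patterns with a
    polarity lexicon, and aggregates labels and opinion pairs into per-flavor
    and per-product sentiment summaries. Includes a synthetic corpus
    generator with planted aspect-overall dependence and planted opinion
    phrases, providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
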
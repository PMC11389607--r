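Package: symplink
Title: Multilingual Symptom Entity Linking and NER Data Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A hybrid pipeline for linking symptom mentions in clinical case
    reports to SNOMED CT concept codes: knowledge-base construction from
    gazetteer, training-set and UMLS alias tables with rare-concept alias
    augmentation, lowercase exact-match dictionary lookup, embedding-based
    candidate generation with an optional sliding-window composite cosine
    score, and large-language-model candidate reranking with a NO_CODE
    fallback. Also provides the data-engineering utilities needed around a
    span-based named entity recogniser: IOB2 encoding and decoding,
    mention-length binned train/validation splits, synonym-replacement
    augmentation, and strict versus overlapping micro-averaged evaluation.
    Synthetic fixture generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
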
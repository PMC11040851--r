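Package: ntiref
Title: Waiting-Time Extraction and Delay Monitoring for Italian Follow-Up Referrals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based pipeline for extracting waiting-time indications
    (Normalized Temporal Information, NTI) from the free-text clinical
    question of Italian follow-up referrals. Implements Italian clinical
    text pre-processing (lower-casing, number-word conversion, pregnancy
    context removal, punctuation pruning, unit lemmatization, edit-distance
    typo correction), a configurable grammar of nested temporal patterns
    (intervals, ranges, precise dates, month-year mentions, bare durations),
    normalization of matches to canonical day counts, delay and postponement
    computation against booking-system dates, cohort aggregation, evaluation
    against gold annotations, and a seeded synthetic-corpus generator for
    end-to-end testing without access to regional data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
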
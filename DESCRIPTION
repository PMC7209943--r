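Package: sniffself
Title: Self-Smelling Questionnaire Analysis and Nasal-Airflow Sniff Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human olfactory self-sampling behaviour.
    Reads, validates and cleans ordinal (never/rarely/occasionally/often)
    self-report questionnaire tables; computes prevalences, sex and
    age-quartile comparisons with a tie-aware two-sample Cramer-von Mises
    statistic, permutation (label-reshuffling) p-values and Benjamini-Hochberg
    false-discovery-rate control; detects sniff events in nasal-airflow traces
    by normalized breath-volume criteria; and generates synthetic survey
    tables and respiration traces with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
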
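Package: perioburden
Title: Cost-of-Illness Estimation for Non-Surgical Periodontal Care Using a
    Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the national economic burden of first-year non-surgical
    periodontal management in specialist clinics from routinely published
    inputs: a care-seeking cascade built from survey prevalences and census
    counts, weighted per-visit direct-medical-cost schedules for public and
    private providers, 3x3 transition matrices over the periodontal health
    states (stable, in remission, unstable) derived from trial-arm summaries
    and published annual probabilities, a 4-cycle irreducible Markov cohort
    model, and deterministic one-way sensitivity scenarios. Includes a
    synthetic-data generator and a patient-level microsimulation oracle so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
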
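Package: fakability
Title: Measuring Faking Ability with Profile Similarity Metrics and Latent
    Variable Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the ability to fake self-report personality
    questionnaires toward job-specific optimal profiles. Links a target
    questionnaire to an anchor questionnaire via item-level correlations and
    regressions, projects expert work-style ratings into veridical optimal
    personality profiles, scores faked responses with profile similarity
    metrics (elevation and shape), and models individual differences with a
    compact maximum-likelihood factor and structural equation engine
    supporting effects-coding identification, full-information maximum
    likelihood for missing data, fit indices, McDonald's omega,
    boundary-adjusted likelihood ratio tests, and bootstrap confidence
    intervals. Includes a synthetic-data generator emulating expert panels,
    faked and honest Likert responses, and bifactor-structured cognitive
    scores so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
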
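Package: conlang
Title: Connected-Language Discourse Analysis for Longitudinal Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing connected-speech (picture-description)
    language samples in longitudinal ageing cohorts. Parses a documented
    subset of CHAT transcripts with C-unit segmentation and maze
    (disfluency) coding, extracts lexical, semantic, syntactic and fluency
    discourse measures, combines them into latent factor scores, and fits
    random-intercept linear mixed models relating factor trajectories to
    early mild cognitive impairment status. Includes synthetic-data
    generators that produce transcripts with exactly known composition and
    simulated two-visit cohorts with recoverable model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
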
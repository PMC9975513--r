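Package: vestscore
Title: Audio-Vestibular Scoring and Phenotyping for Sudden Sensorineural
    Hearing Loss Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores and phenotypes cohorts of patients with sudden
    sensorineural hearing loss (SSNHL) from their audio-vestibular test
    battery. Computes pure-tone averages over the four most impaired
    contiguous bone-conduction frequencies, hearing-loss degree and
    configuration, SSNHL eligibility, and hearing-recovery outcomes;
    derives VEMP asymmetry ratios, frequency tuning, video head-impulse
    canal impairment calls and otolith/canal lesion patterns; classifies
    clinical-course subgroups, arterial ("vascular") lesion patterns and a
    cardiovascular risk score; and runs the cohort-level statistics
    (contingency tabulations, chi-square/Fisher, Kruskal-Wallis with Dunn
    post-hoc, Spearman recovery trend, logistic regression of recovery).
    Includes a seeded synthetic-cohort generator emulating the
    three-subgroup study structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    data.table,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
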
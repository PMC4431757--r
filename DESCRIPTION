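Package: obesityDEA
Title: Efficiency-Score and Genetic-Risk Modelling of Obesity with Data
    Envelopment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-individual obesity risk by treating each cohort
    subject as a decision-making unit in an input-oriented, constant
    returns-to-scale (Charnes-Cooper-Rhodes) data envelopment analysis:
    physical-activity energy expenditure and the inverse of caloric intake
    are the inputs and the inverse of body mass index is the output, so an
    efficiency score of 1 marks subjects on the empirical
    calorie-conversion frontier.  Also computes a weighted genetic
    predisposition score from SNP effect-allele dosages (with minor allele
    frequency and call-rate quality filters), compares five robust linear
    regression models of baseline BMI or yearly BMI change on environment,
    efficiency, and genetic scores, and ships a calibrated synthetic
    cohort generator so the full pipeline is testable without subject-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    pracma,
    jsonlite,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
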
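Package: germscreen
Title: Time-Course Metabolomics Screening of Germination-Associated
    Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative time-course metabolomics pipeline for screening
    metabolites associated with seed germination in two varieties with
    different germination speeds. Provides replicate quality control by
    inter-replicate Pearson concordance, segmentation of the germination
    time course into metabolome stages with between-variety lag
    estimation, three parallel candidate filters (trait correlation,
    coefficient of variation, differential accumulation with
    Benjamini-Hochberg correction) intersected into a candidate set,
    z-score trajectory-pattern classification, annotation against two
    germination-related metabolic modules, germination-physiology
    statistics, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
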
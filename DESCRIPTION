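Package: langscore
Title: Automated Scoring and Feature Extraction for Cognitive Language Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated scorers for six cognitive language-assessment tasks
    (image naming, picture description, verbal fluency, story recall,
    vocabulary definition, and binary choice tasks), together with a
    multi-family linguistic feature extractor (lexical richness,
    readability, norms, part-of-speech profiles, syntactic complexity
    ratios, Yngve depth, utterance-level semantic similarity, and
    pause/duration features from word alignments), per-stimulus
    empirical-CDF score equalization, simplicity-weighted averaging for
    binary tasks, cross-task correlation analysis, and canonical-correlation
    multi-view augmentation. Seeded synthetic-fixture generators (toy is-a
    taxonomies, norm lexicons, transcripts, score cohorts) let the full
    pipeline run and be tested entirely offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
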
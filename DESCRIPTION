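Package: glandtools
Title: Transcriptome Subtraction and Defensive-Chemistry Analysis for Beetle Stink Glands
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for odoriferous (stink) gland studies in
    tenebrionid beetles. Computes sequencing-library metrics and per-gene
    read coverage, classifies genes into ten mutually exclusive
    gland-specificity groups by log2 fold-change subtraction, quantifies
    benzoquinone and alkene gland volatiles from GC-MS peak areas via
    external standard calibration (including equivalents for compounds
    without authentic standards), scores RNAi knock-down phenotype
    strength from per-beetle chemical changes, and estimates phenol
    oxidase activity as the maximal linear-phase slope of microplate
    kinetic traces. Ships seeded synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
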
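Package: crisprRepair
Title: Repair-Pathway Classification of CRISPR Editing Outcomes in Embryo Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies edited alleles from amplicon genotyping of
    CRISPR/Cas9 embryo experiments into non-homologous end joining (NHEJ),
    microhomology-mediated end joining (MMEJ), homology-directed repair
    (HDR) and unedited categories using junction-microhomology detection
    on left-normalized deletions. Aggregates per-embryo and per-guide
    statistics (editing efficiency, NHEJ/MMEJ ratio, repair-bias classes,
    knock-in positive rates and fold changes), provides variant-caller
    consensus, donor-integration breakpoint thresholding and cut-site
    coverage-loss bookkeeping, and ships a seeded synthetic-cohort
    generator with ground-truth repair labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
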
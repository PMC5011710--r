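Package: prfscan
Title: Proteogenomic Detection of +1 Programmed Ribosomal Frameshifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects +1 programmed ribosomal frameshift (PRF) sites in
    ciliate transcripts and verifies them against shotgun proteomics data.
    Implements the Euplotes variant genetic code (UGA reassigned to
    cysteine), slippery-motif scanning and frameshift-joined gene models
    with up to three junctions per gene, multi-protease in-silico digestion
    (trypsin, GluC, chymotrypsin) with fixed and variable modifications,
    b/y fragment-ion matching of MGF peak lists under ppm/Da tolerances
    with target-decoy false discovery rate control, peptide-to-frame
    evidence classification with frameshift-site localization and +1
    versus -2 discrimination by theoretical mass, and a seed-deterministic
    synthetic-data generator that emulates a macronuclear transcriptome
    and its LC-MS/MS readout for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
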
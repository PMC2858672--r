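Package: mspa
Title: Single-Molecule Footprinting and Methylation Analysis of LINE-1
    Antisense Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the chromatin and methylation state of
    individual LINE-1 (L1) antisense promoters from single-molecule
    bisulfite data. Implements methylase-dependent single promoter
    analysis (M-SPA): GpC-methyltransferase accessibility calling with
    GpCpG exclusion, per-molecule nucleosome footprint inference, and
    classification of the bidirectional L1 promoter into
    tetranucleosomal, dinucleosomal, and open occupancy states. Also
    provides locus-specific bisulfite methylation quantification
    (percent methylation, percent fully unmethylated strands, biphasic
    strand distributions), Mann-Whitney and ROC cohort comparisons, a
    candidate antisense-L1 promoter scanner, and a fully seeded
    synthetic-data generator covering molecules, enzyme treatment,
    bisulfite conversion, MNase fragmentation, cohorts, and annotated
    genomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
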
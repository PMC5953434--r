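Package: bbbqc
Title: Reference-Gene Stability and Purity Assessment for Brain Microvessel RT-qPCR
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An evaluation platform for real-time RT-qPCR of isolated brain
    microvessel (BrMV) and capillary-depleted brain (CDB) preparations.
    Implements reference-gene stability selection by the geNorm pairwise-
    variation statistic (M) and the BestKeeper descriptive index, standard-
    curve fitting with amplification-efficiency estimation, relative (delta-
    delta-Ct) and absolute (copy-number) quantification, marker-gene-based
    relative-purity calibration and scoring with a Plvap fenestrated-vessel
    indicator, and cross-validation against immunofluorescence cell-composition
    counts. A seeded synthetic-data generator emulates the measurement process
    (cell-type mixtures, marker enrichment, allele dosage, dilution and mixing
    series, replicate noise) so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
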
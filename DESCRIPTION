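Package: gelsilac
Title: Quantitative Analysis of GeLC-SILAC Proteomics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-identification quantitative analysis for SILAC experiments
    separated on SDS-PAGE gels (GeLC-MS/MS). Takes peptide-level light/heavy
    quantification events scattered across molecular-weight-ordered gel bands
    and produces protein-level log2 abundance ratios by band-wise averaging,
    median normalization, Z-statistic p-values, target-decoy false discovery
    rates, cross-fraction merging, band-resolved proteoform quantification
    (precursor versus processed enzyme forms), and category summaries.
    Includes sequence utilities (in-silico tryptic digestion, monoisotopic
    mass arithmetic with SILAC label shifts, decoy shuffling, sequence
    coverage) and a ground-truthed synthetic-data generator so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
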
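Package: deamprofiler
Title: Sequence-Context Profiling and Editing Quantification for
    Double-Stranded DNA Cytidine Deaminases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize double-stranded DNA cytidine deaminases
    and TALE-fused mitochondrial base editors. Includes triage of candidate
    deaminases by C-terminal SPKK-related DNA-binding motifs with
    score-plus-diversity ranking; genome-wide deamination sequence-context
    profiling from per-base pileups (binomial variant filtering,
    strand-normalized flanking contexts, probability logos, IUPAC
    preference calls); per-position editing-efficiency and indel
    quantification from targeted amplicon reads; and mitochondrial
    genome-wide off-target editing statistics with on-target and cell-line
    SNV exclusions. A synthetic-data module generates mutagenized genomes,
    treated and untreated mitochondrial pileups, amplicon read sets and
    candidate protein panels with known ground truth, so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
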
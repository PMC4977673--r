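Package: glycoMapper
Title: Mapping and Profiling of N-Glycosylation Sites in Fungal Secretomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for N-glycoproteomic analysis of fungal secretomes:
    rule-based scanning of N-X-S/T sequons in protein sequences, in-silico
    tryptic digestion with monoisotopic mass bookkeeping for the +203 Da
    GlcNAc-remnant modification left by Endo H, three-class evidence
    classification of predicted sites (validated, non-validated,
    non-covered), flanking-sequence motif reports and chemical-class
    profiles, conservation of glycosylation sites across homolog multiple
    alignments, composition assignment of permethylated sodiated N-glycan
    MALDI peak lists, and spectral-count secretome summaries. A synthetic
    secretome generator with known ground truth (site occupancy, homolog
    retention, glycan pool composition) makes every stage testable without
    raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
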
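Package: rhoterm
Title: Prediction of Rho-Dependent Transcription Terminators in Bacterial
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans bacterial genome sequences for putative Rho-dependent
    transcription terminators using a two-step motif search: a 78-nt
    Rho-utilization (RUT) site with C-over-G skew and regularly spaced
    cytosines, refined within a 128-nt region, followed by a putative RNA
    polymerase pause site (a GC-rich stem-loop hairpin or the
    G(-11)G(-10)(C/T)(-1)G(+1) pause consensus element) in the 150 nt
    downstream.  Each prediction receives a score between 6 and 15 from a
    fixed bonus schedule.  Includes the accompanying evaluation protocol
    (positive/negative sequence-set construction, balanced repeated
    subsampling with the five standard classification metrics, RNA-seq
    coverage-gradient validation, inter-predictor overlap counting) and a
    seeded synthetic-genome generator with planted terminators and coverage
    tracks for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
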
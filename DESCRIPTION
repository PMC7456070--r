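Package: prfscan
Title: Detection of -1 Programmed Ribosomal Frameshift Signals and
    Frameshift-Linked Transcript Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans coding sequences for slippery heptamers (X XXY YYZ) and
    attributes them to their decoding tRNAs (phenylalanine UUUU/C,
    lysine AAAA/G), scores the downstream stimulatory RNA structure by
    base-pair maximization with a mononucleotide-shuffle permutation null,
    simulates the -1 ribosomal slip to locate premature termination codons,
    predicts nonsense-mediated decay by the exon-junction distance rule,
    and tests whether down-regulated transcripts are enriched for
    tRNA-Phe slippery signals with an exact hypergeometric test and a
    negative-control panel. Includes dual-luciferase and dual-GST
    frameshift-reporter quantification and a synthetic transcriptome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
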
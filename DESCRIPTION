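Package: prionScan
Title: Detection of Q/N-Rich Prion-Like Domains and Their Amyloid Nucleating Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for glutamine/asparagine (Q/N) rich
    prion-like domains (PrLDs). Candidate domains must sit in an intrinsically
    disordered region of at least 60 residues (sliding-window fold-index
    prediction), carry a contiguous stretch of Q/N enrichment above a tunable
    threshold, and contain a 21-residue amyloid nucleating core whose
    position-specific scoring-matrix score exceeds a cut-off. Includes FASTA
    batch scanning with CSV output, confusion-matrix benchmarking with a score
    cut-off sweep, and deterministic synthetic sequence generators with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
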
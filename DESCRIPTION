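Package: oligotiler
Title: Oligomer Tiling Design for Polymerase Chain Assembly
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splits a target DNA sequence into an ordered set of
    alternating-strand, overlapping oligomers suitable for polymerase chain
    assembly (PCA). Every candidate oligomer is scored with a penalty that
    combines the deviation of its annealing-overlap melting temperature from a
    user target (nearest-neighbor thermodynamics, unified SantaLucia parameter
    set), a 3'-terminal thymine indicator, GC-clamp excess at the annealing
    end, and within-oligomer and between-overlap repeat content; oligomers
    whose overlaps share repeated k-mers are segregated into sub-pool clusters
    to limit cross-hybridization during assembly. Includes in-silico design
    verification (target reconstruction and cross-hybridization screening),
    per-oligomer re-optimization, CSV export of 5'-to-3' sequences,
    deterministic synthetic-sequence fixtures, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
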
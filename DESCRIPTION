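Package: divscan
Title: Detection of Divergent Regions and Putative SNPs in Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects small divergent (and conserved) regions and putative
    SNPs in multiple sequence alignments of closely related DNA or protein
    sequences. Four per-column scores (weighted, DNAW, entropy,
    variability) are thresholded with robust median-absolute-deviation
    cutoffs; a fast-Fourier-transform low-pass filter turns per-column
    peaks into region-scale signals. Divergent windows feed a PCR primer
    grading module (GC content, nearest-neighbor melting temperature,
    GC clamp, repeats, self-dimer and hairpin free energies). Alignments
    are read from FASTA, Clustal, PHYLIP, MSF or NEXUS with content-based
    format sniffing; results are exported as GFF3, TSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    seqinr,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
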
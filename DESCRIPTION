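Package: fpmap
Title: Fingerprint-Based BAC Physical Map Construction and Anchoring
Version: 0.1.0
Authors@R: person("PGML", "Toolkit", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building genome physical maps from BAC restriction
    fingerprints. Implements Sulston-score overlap calling for agarose and
    high-information-content (HICF) fingerprints, FPC-style contig assembly
    with marker- and HICF-aware cutoff relaxation, consensus-band (CB) map
    construction, Q-clone splitting, end-merging, singleton adoption and
    clone burying, pooled overgo hybridization deconvolution on a row/column/
    diagonal grid, anchoring of contigs onto consensus genetic maps, and
    window-based anchoring of contigs onto comparator genome sequences.
    Includes analytic calculators (minimum matching-band thresholds,
    Lander-Waterman expected contig counts), a synthetic genome/BAC-library
    simulator with full ground truth for validation, and a command-line
    interface chaining the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Biostrings,
    withr
Config/testthat/edition: 3
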
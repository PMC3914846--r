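Package: uorfscan
Title: Detection and Conservation Analysis of Upstream Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates upstream open reading frames (uORFs) in eukaryotic mRNA
    transcripts, screens them for cross-species conservation at the peptide
    level against a locally built uORF database, aligns transcript pairs
    globally with user-specified scores, computes a sliding-window percent
    identity profile rendered as an annotated heatmap, and estimates
    synonymous and non-synonymous substitution rates (NG86 and YN00) for
    both the uORF and the main coding sequence so that selective pressure on
    a candidate uORF can be compared against the main ORF as an internal
    control. Includes a deterministic synthetic transcript generator with
    planted conservation structure for benchmarking, and a command-line
    interface over the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    png,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
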
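#' Parameters for the uORF search
#'
#' @param min_len_codons Minimum uORF length in coding codons (the stop
#'   codon is not counted). Default 10: shorter peptides carry too little
#'   signal for the downstream conservation statistics.
#' @param max_overlap_nt Maximum number of nucleotides a uORF may extend 3'
#'   of the mORF start codon. Default 0 (uORFs fully upstream).
#' @param search_limit_nt Optional: consider only uAUGs within the first
#'   `search_limit_nt` nucleotides of the transcript.
#' @return An object of class `uorf_search_params`.
#' @export
uorf_search_params <- function(min_len_codons = 10L, max_overlap_nt = 0L,
                               search_limit_nt = NULL) {
  min_len_codons <- as.integer(min_len_codons)
  max_overlap_nt <- as.integer(max_overlap_nt)
  if (is.na(min_len_codons) || min_len_codons < 1L)
    stop("min_len_codons must be >= 1", call. = FALSE)
  if (is.na(max_overlap_nt) || max_overlap_nt < 0L)
    stop("max_overlap_nt must be >= 0", call. = FALSE)
  if (!is.null(search_limit_nt)) {
    search_limit_nt <- as.integer(search_limit_nt)
    if (is.na(search_limit_nt) || search_limit_nt < 1L)
      stop("search_limit_nt must be >= 1 when given", call. = FALSE)
  }
  structure(list(min_len_codons = min_len_codons,
                 max_overlap_nt = max_overlap_nt,
                 search_limit_nt = search_limit_nt),
            class = "uorf_search_params")
}

# All ATG positions (0-based) in a sequence string.
atg_positions <- function(seq) {
  hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

# First in-frame stop at/after 0-based position `from`; returns the 0-based
# exclusive end of the stop codon, or NA if the frame runs off the transcript
# without terminating.
first_inframe_stop_end <- function(seq, from) {
  n <- nchar(seq)
  if (from + 3L > n) return(NA_integer_)
  starts <- seq.int(from + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]] + 2L
}

#' Locate the main ORF of a transcript
#'
#' Returns the annotated CDS when present. Otherwise the longest
#' AUG-initiated, stop-terminated ORF in any of the three forward frames is
#' taken as the mORF, with ties broken in favour of the 5'-most start — the
#' usual working definition of the main coding sequence on an mRNA.
#'
#' @param t A [transcript()].
#' @return An [orf_interval()] (including the stop codon).
#' @export
find_morf <- function(t) {
  stopifnot(inherits(t, "transcript"))
  if (!is.null(t$cds)) return(t$cds)
  starts <- atg_positions(t$sequence)
  best <- NULL
  for (s in starts) {
    e <- first_inframe_stop_end(t$sequence, s)
    if (is.na(e)) next
    if (is.null(best) || (e - s) > (best$end - best$start))
      best <- orf_interval(s, e)
  }
  if (is.null(best))
    stop(sprintf("no-mORF: transcript '%s' has no AUG-initiated, stop-terminated ORF",
                 t$accession), call. = FALSE)
  best
}

#' Find upstream ORFs on a transcript
#'
#' Every AUG whose position is strictly 5' of the mORF start opens a
#' candidate uORF. A candidate is kept when (i) an in-frame stop codon
#' occurs within the transcript, at most `max_overlap_nt` nucleotides 3' of
#' the mORF start; (ii) it codes for at least `min_len_codons` codons
#' (excluding the stop); and (iii) when `search_limit_nt` is set, its uAUG
#' lies within that 5' prefix. Candidates without an in-frame stop are
#' dropped: they are N-terminal extensions of the mORF, not discrete
#' uORF-encoded peptides. Nested uORFs are reported independently.
#'
#' @param t A [transcript()].
#' @param p A [uorf_search_params()].
#' @return A data frame with one row per uORF, sorted by start: `accession`,
#'   `start`, `end` (0-based half-open; see [uorf_table()] for 1-based
#'   display), `frame`, `length_codons` (coding codons), `overlap_nt`
#'   (nucleotides extending past the mORF start), `peptide`.
#' @export
find_uorfs <- function(t, p = uorf_search_params()) {
  stopifnot(inherits(t, "transcript"), inherits(p, "uorf_search_params"))
  morf <- find_morf(t)
  starts <- atg_positions(t$sequence)
  starts <- starts[starts < morf$start]
  if (!is.null(p$search_limit_nt))
    starts <- starts[starts < p$search_limit_nt]
  rows <- lapply(starts, function(s) {
    e <- first_inframe_stop_end(t$sequence, s)
    if (is.na(e)) return(NULL)
    overlap <- max(0L, e - morf$start)
    len_codons <- (e - s) %/% 3L - 1L
    if (overlap > p$max_overlap_nt || len_codons < p$min_len_codons)
      return(NULL)
    data.frame(accession = t$accession, start = s, end = e, frame = s %% 3L,
               length_codons = len_codons, overlap_nt = overlap,
               peptide = translate_nt(substr(t$sequence, s + 1L, e - 3L)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_uorf_frame())
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

empty_uorf_frame <- function() {
  data.frame(accession = character(0), start = integer(0), end = integer(0),
             frame = integer(0), length_codons = integer(0),
             overlap_nt = integer(0), peptide = character(0),
             stringsAsFactors = FALSE)
}

#' uORF report table with 1-based inclusive coordinates
#'
#' @param uorfs Output of [find_uorfs()].
#' @return Data frame with `start`/`end` converted to 1-based inclusive
#'   (GenBank-style) coordinates for display and TSV export.
#' @export
uorf_table <- function(uorfs) {
  out <- uorfs
  out$start <- out$start + 1L
  out
}
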
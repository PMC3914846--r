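# Independent brute-force oracles used to validate the implementation.
# These share no code with the package internals.

# --- global affine-gap alignment score (Gotoh, plain R) --------------------
# Gap run of length L costs open + ext * (L - 1), end gaps penalised.
oracle_global_score <- function(q, r, match = 5, mismatch = -4,
                                open = 50, ext = 0) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)   # X: gap in r, Y: gap in q
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -open - ext * (i - 1)
    M[i + 1, 1] <- NEG
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -open - ext * (j - 1)
    M[1, j + 1] <- NEG
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (qc[i] == rc[j] && qc[i] != "N") match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext,
                           Y[i, j + 1] - open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - open,
                           Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- local peptide alignment score (Smith-Waterman, plain R) ---------------
# BLOSUM62, gap of length L costs open + ext * L (BLAST-style costs).
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  NEG <- -1e9
  E[] <- NEG; F[] <- NEG
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + B[ac[i], bc[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# --- exhaustive uORF enumeration ------------------------------------------
# Every ATG strictly 5' of the mORF start opens a candidate; scan codons to
# the first stop; apply the stop/overlap/length/search-limit filters.
oracle_find_uorfs <- function(seq, morf_start, min_len, max_overlap,
                              search_limit = NULL) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  rows <- list()
  for (s in 0:(morf_start - 1)) {
    if (s + 3 > n || substr(seq, s + 1, s + 3) != "ATG") next
    if (!is.null(search_limit) && s >= search_limit) next
    e <- NA
    k <- s
    while (k + 3 <= n) {
      if (substr(seq, k + 1, k + 3) %in% stops) { e <- k + 3; break }
      k <- k + 3
    }
    if (is.na(e)) next
    overlap <- max(0, e - morf_start)
    len <- (e - s) / 3 - 1
    if (overlap > max_overlap || len < min_len) next
    pep <- character(0)
    gc <- Biostrings::GENETIC_CODE
    for (k in seq(s, e - 6, by = 3)) {
      cod <- substr(seq, k + 1, k + 3)
      pep <- c(pep, if (cod %in% names(gc)) gc[[cod]] else "X")
    }
    rows[[length(rows) + 1]] <- data.frame(
      start = s, end = e, length_codons = len, overlap_nt = overlap,
      peptide = paste(pep, collapse = ""), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      length_codons = integer(0), overlap_nt = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# --- clipped-window identity profile --------------------------------------
# For each non-gap query column i, average M over the window [i-z, i+z]
# clipped to [1, m].
oracle_profile <- function(q_aligned, M, w) {
  z <- w %/% 2
  m <- length(M)
  qc <- strsplit(q_aligned, "")[[1]]
  vals <- c()
  for (i in seq_len(m)) {
    if (qc[i] == "-") next
    win <- max(1, i - z):min(m, i + z)
    vals <- c(vals, mean(M[win]))
  }
  vals
}

# --- NG86 pathway-averaged difference counts ------------------------------
# Recursive enumeration of all orderings of the differing positions;
# pathways through stop codons are excluded (all pathways used, with steps
# through stops non-synonymous, when every pathway is blocked).
oracle_path_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  aa <- function(x) if (x %in% stops) "*" else gc[[x]]
  walk <- function(cur, remaining, forbid_stops) {
    if (!length(remaining)) return(list(c(sd = 0, nd = 0)))
    res <- list()
    for (idx in seq_along(remaining)) {
      pos <- remaining[idx]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (forbid_stops && nxt %in% stops && length(remaining) > 1) next
      step <- if (aa(cur) == aa(nxt)) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tail in walk(nxt, remaining[-idx], forbid_stops))
        res[[length(res) + 1]] <- step + tail
    }
    res
  }
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  paths <- walk(c1, diffpos, TRUE)
  if (!length(paths)) paths <- walk(c1, diffpos, FALSE)
  Reduce(`+`, paths) / length(paths)
}

# random DNA string helper
rand_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
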
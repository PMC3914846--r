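STOP_CODONS <- c("TAA", "TAG", "TGA")

# Standard genetic code lookup (DNA codons), taken from Biostrings at load time
# so translation stays in step with the canonical table.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
}

#' Half-open ORF interval on a transcript
#'
#' Internal coordinates are 0-based half-open (`[start, end)`); all
#' user-facing tables are converted to 1-based inclusive on output. The
#' reading frame is derived as `start %% 3`. For a complete ORF the interval
#' includes the terminating stop codon, so `end - start` is a multiple of 3.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return An object of class `orf_interval`.
#' @export
orf_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid ORF interval: need 0 <= start < end", call. = FALSE)
  structure(list(start = start, end = end, frame = start %% 3L),
            class = "orf_interval")
}

#' @export
print.orf_interval <- function(x, ...) {
  cat(sprintf("<orf_interval> %d..%d (1-based), frame %d, %d nt\n",
              x$start + 1L, x$end, x$frame, x$end - x$start))
  invisible(x)
}

#' An mRNA transcript
#'
#' Sense-strand nucleotide sequence over the alphabet A, C, G, T, N. On
#' ingest U is normalised to T, lower case to upper case, and any other
#' IUPAC ambiguity code to N. An annotated CDS (the mORF), when present,
#' must be a positive multiple of 3 in length and lie within the sequence.
#'
#' @param accession Text identifier.
#' @param sequence Nucleotide string.
#' @param cds Optional [orf_interval()] giving the annotated mORF.
#' @param species Optional species label.
#' @param morf_undefined Flag set by [read_genbank()] when the CDS start is
#'   unannotated or fuzzy; such records are excluded by [build_uorf_db()].
#' @return An object of class `transcript`.
#' @export
transcript <- function(accession, sequence, cds = NULL, species = NULL,
                       morf_undefined = FALSE) {
  sequence <- normalise_sequence(sequence, accession)
  if (!is.null(cds)) {
    stopifnot(inherits(cds, "orf_interval"))
    if (cds$end > nchar(sequence))
      stop(sprintf("record '%s': CDS extends past sequence end", accession),
           call. = FALSE)
    if ((cds$end - cds$start) %% 3L != 0L)
      stop(sprintf("record '%s': CDS length is not a multiple of 3", accession),
           call. = FALSE)
  }
  structure(list(accession = as.character(accession), sequence = sequence,
                 cds = cds, species = species,
                 morf_undefined = isTRUE(morf_undefined)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s: %d nt%s%s\n", x$accession, nchar(x$sequence),
              if (!is.null(x$cds))
                sprintf(", CDS %d..%d", x$cds$start + 1L, x$cds$end) else "",
              if (x$morf_undefined) " [mORF start undefined]" else ""))
  invisible(x)
}

# U->T, case folding, ambiguity codes -> N; rejects non-IUPAC characters.
normalise_sequence <- function(x, accession = "<sequence>") {
  x <- toupper(gsub("[ \t\r\n0-9]", "", as.character(x)))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", x)
  if (nchar(bad) > 0)
    stop(sprintf("record '%s': illegal character(s) '%s' in sequence",
                 accession, substr(bad, 1, 10)), call. = FALSE)
  x <- gsub("[RYSWKMBDHV]", "N", x)
  if (!nzchar(x))
    stop(sprintf("record '%s': empty sequence", accession), call. = FALSE)
  x
}

#' Read transcripts from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file, wrapped or unwrapped.
#' @return A list of [transcript()] objects (no CDS annotation).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (length(set) == 0) stop("empty FASTA input: ", path, call. = FALSE)
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  out <- vector("list", length(set))
  for (k in seq_along(set))
    out[[k]] <- transcript(acc[k], as.character(set[[k]]))
  names(out) <- acc
  out
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A `transcript` or list of them.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  transcripts <- as_transcript_list(transcripts)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in transcripts) {
    writeLines(paste0(">", t$accession), con)
    s <- t$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

as_transcript_list <- function(x) {
  if (inherits(x, "transcript")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "transcript")))
  if (is.null(names(x)))
    names(x) <- vapply(x, `[[`, "", "accession")
  x
}

#' Read transcripts from a GenBank flat file
#'
#' Parses LOCUS/ACCESSION, the first CDS feature and the ORIGIN sequence of
#' each record. GenBank CDS locations `a..b` are 1-based inclusive and are
#' stored as 0-based half-open intervals (`start = a-1`, `end = b`). Records
#' whose CDS start is fuzzy (e.g. `<1..200`) or that carry no CDS feature at
#' all are returned with `morf_undefined = TRUE` so the database builder can
#' exclude them. A `join(...)` location is collapsed to its outer span
#' (genome-coordinate exon structure is out of scope for mRNA records).
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return A list of [transcript()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank input: ", path, call. = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) stop("malformed GenBank file (no record terminator '//'): ",
                          path, call. = FALSE)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:ends[k]]
    if (!any(grepl("^LOCUS", rec))) next   # trailing blank chunk
    t <- parse_genbank_record(rec, path)
    if (is.null(t)) next
    out[[t$accession]] <- t
  }
  if (!length(out)) stop("no usable GenBank records in ", path, call. = FALSE)
  out
}

parse_genbank_record <- function(rec, path) {
  locus <- grep("^LOCUS", rec, value = TRUE)
  name <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                      "\\s+")[[1]][1] else NA_character_
  accline <- grep("^ACCESSION", rec, value = TRUE)
  acc <- if (length(accline))
    strsplit(trimws(sub("^ACCESSION", "", accline[1])), "\\s+")[[1]][1]
  else name
  if (is.na(acc) || !nzchar(acc))
    stop("unparsable GenBank record (no LOCUS/ACCESSION) in ", path,
         call. = FALSE)
  org <- grep("^\\s+ORGANISM", rec, value = TRUE)
  species <- if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1])) else NULL

  ori <- grep("^ORIGIN", rec)
  if (!length(ori)) {
    warning("GenBank record '", acc, "' has no sequence; skipped")
    return(NULL)
  }
  seqlines <- rec[(ori[1] + 1L):length(rec)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  sequence <- paste(gsub("[^A-Za-z]", "", seqlines), collapse = "")
  if (!nzchar(sequence)) {
    warning("GenBank record '", acc, "' has no sequence; skipped")
    return(NULL)
  }

  loc <- genbank_first_cds_location(rec)
  cds <- NULL
  morf_undefined <- TRUE
  if (!is.null(loc)) {
    fuzzy_start <- grepl("<", loc, fixed = TRUE)
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) >= 2) {
      a <- min(nums); b <- max(nums)
      if (!fuzzy_start && b > a && (b - a + 1L) %% 3L == 0L &&
          b <= nchar(gsub("[^A-Za-z]", "", sequence))) {
        cds <- orf_interval(a - 1L, b)
        morf_undefined <- FALSE
      }
    }
  }
  transcript(acc, sequence, cds = cds, species = species,
             morf_undefined = morf_undefined)
}

# Location string of the first CDS feature, joining continuation lines.
genbank_first_cds_location <- function(rec) {
  i <- grep("^\\s{5}CDS\\s+\\S", rec)
  if (!length(i)) return(NULL)
  i <- i[1]
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", rec[i]))
  j <- i + 1L
  while (j <= length(rec) && grepl("^\\s{10,}[^/]", rec[j]) &&
         !grepl("^\\s{5}\\S", rec[j])) {
    loc <- paste0(loc, trimws(rec[j]))
    j <- j + 1L
  }
  loc
}

#' Write transcripts as a minimal GenBank flat file
#'
#' Emits LOCUS, ACCESSION, an optional ORGANISM line, a CDS feature and the
#' ORIGIN block. Transcripts flagged `morf_undefined` are written with a
#' fuzzy CDS start (`<1..n`) when they carry a CDS, or with no CDS feature,
#' mirroring the RefSeq records the exclusion rule targets.
#'
#' @param transcripts A `transcript` or list of them.
#' @param path Output path.
#' @export
write_genbank <- function(transcripts, path) {
  transcripts <- as_transcript_list(transcripts)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in transcripts) {
    n <- nchar(t$sequence)
    writeLines(sprintf("LOCUS       %s %d bp    mRNA    linear   25-SEP-2026",
                       t$accession, n), con)
    writeLines(sprintf("ACCESSION   %s", t$accession), con)
    if (!is.null(t$species)) {
      writeLines("SOURCE      synthetic construct", con)
      writeLines(sprintf("  ORGANISM  %s", t$species), con)
    }
    writeLines("FEATURES             Location/Qualifiers", con)
    if (!is.null(t$cds)) {
      loc <- if (t$morf_undefined)
        sprintf("<1..%d", t$cds$end) else
        sprintf("%d..%d", t$cds$start + 1L, t$cds$end)
      writeLines(sprintf("     CDS             %s", loc), con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(t$sequence)
    for (off in seq(1L, n, by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, n))
      tens <- seq(1L, nchar(chunk), by = 10L)
      blocks <- substring(chunk, tens, pmin(tens + 9L, nchar(chunk)))
      writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# Translate an in-frame stretch of nucleotides; codons containing N give 'X',
# stop codons give '*'.
translate_nt <- function(seq_nt) {
  n <- nchar(seq_nt) - nchar(seq_nt) %% 3L
  if (n < 3L) return("")
  codons <- substring(seq_nt, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- codon_table()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
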
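# Karlin-Altschul parameters for gapped BLOSUM62 with gap costs 11/1 —
# the published values used to express a raw local-alignment score as a
# bit-like score and a database-size-aware expectation.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Build a uORF database from reference transcripts
#'
#' Extracts every qualifying uORF (under `p`) from each transcript whose
#' mORF start is defined, storing peptide sequences for translated search.
#' Records flagged as mORF-start-undefined (fuzzy or missing CDS in their
#' GenBank source) are excluded and counted, as are records on which no
#' mORF can be located at all.
#'
#' @param transcripts List of [transcript()] objects.
#' @param p A [uorf_search_params()].
#' @param version_tag Optional database version label; defaults to a digest
#'   of the input sequences and build parameters.
#' @return An object of class `uorf_db`: `records` (uORF data frame),
#'   `transcripts` (the retained source transcripts, needed for downstream
#'   pairwise mRNA alignment), `source_meta` (build parameters, input
#'   digest, exclusion count), `version_tag`.
#' @export
build_uorf_db <- function(transcripts, p = uorf_search_params(),
                          version_tag = NULL) {
  transcripts <- as_transcript_list(transcripts)
  if (!length(transcripts)) stop("no input transcripts", call. = FALSE)
  usable <- list(); n_excluded <- 0L
  records <- list()
  for (t in transcripts) {
    if (t$morf_undefined) { n_excluded <- n_excluded + 1L; next }
    u <- tryCatch(find_uorfs(t, p), error = function(e) NULL)
    if (is.null(u)) { n_excluded <- n_excluded + 1L; next }
    usable[[t$accession]] <- t
    if (nrow(u)) records[[t$accession]] <- u
  }
  if (!length(usable))
    stop("empty database: no transcript with a defined mORF", call. = FALSE)
  recs <- if (length(records)) do.call(rbind, c(records, make.row.names = FALSE))
  else empty_uorf_frame()
  digest <- content_digest(c(vapply(usable, `[[`, "", "sequence"),
                             sprintf("%d|%d|%s", p$min_len_codons,
                                     p$max_overlap_nt,
                                     p$search_limit_nt %||% "NA")))
  structure(list(
    records = recs, transcripts = usable,
    source_meta = list(params = p, n_input = length(transcripts),
                       n_excluded = n_excluded, input_digest = digest),
    version_tag = version_tag %||% paste0("uorfdb-", substr(digest, 1, 12))),
    class = "uorf_db")
}

# md5 of concatenated content (via a temp file; base R has no in-memory md5)
content_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' @export
print.uorf_db <- function(x, ...) {
  cat(sprintf("<uorf_db> %s: %d uORF peptides from %d transcripts (%d excluded)\n",
              x$version_tag, nrow(x$records), length(x$transcripts),
              x$source_meta$n_excluded))
  invisible(x)
}

#' Persist a uORF database as a plain-text bundle
#'
#' Writes `peptides.fasta` (headers `accession|start-end|overlap_nt`, 1-based
#' inclusive coordinates), `transcripts.fasta` and `meta.yaml`.
#'
#' @param db A `uorf_db`.
#' @param dir Output directory (created if needed).
#' @export
write_uorf_db <- function(db, dir) {
  stopifnot(inherits(db, "uorf_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "peptides.fasta"), "w")
  if (nrow(db$records))
    for (i in seq_len(nrow(db$records)))
      writeLines(c(sprintf(">%s|%d-%d|%d", db$records$accession[i],
                           db$records$start[i] + 1L, db$records$end[i],
                           db$records$overlap_nt[i]),
                   db$records$peptide[i]), con)
  close(con)
  write_fasta(db$transcripts, file.path(dir, "transcripts.fasta"))
  p <- db$source_meta$params
  yaml::write_yaml(list(
    version_tag = db$version_tag, input_digest = db$source_meta$input_digest,
    n_input = db$source_meta$n_input, n_excluded = db$source_meta$n_excluded,
    min_len_codons = p$min_len_codons, max_overlap_nt = p$max_overlap_nt,
    search_limit_nt = p$search_limit_nt),
    file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a uORF database written by [write_uorf_db()]
#'
#' @param dir Database directory.
#' @return A `uorf_db`.
#' @export
read_uorf_db <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  transcripts <- read_fasta(file.path(dir, "transcripts.fasta"))
  p <- uorf_search_params(meta$min_len_codons, meta$max_overlap_nt,
                          meta$search_limit_nt)
  db <- build_uorf_db(transcripts, p, version_tag = meta$version_tag)
  db$source_meta$n_excluded <- meta$n_excluded
  db$source_meta$n_input <- meta$n_input
  db
}

#' Default raw-score threshold for the translated search
#'
#' Chooses the smallest raw Smith-Waterman score whose Karlin-Altschul
#' expectation against a database of `db_residues` peptide residues is below
#' `alpha`, for a typical query peptide of `peptide_len` residues. With the
#' defaults this keeps the chance that a random short peptide hits a
#' 10,000-record database below 5%.
#'
#' @param peptide_len Typical query peptide length.
#' @param db_residues Total residues in the database.
#' @param alpha Tolerated expectation of a random hit.
#' @return Integer score threshold.
#' @export
calibrate_min_score <- function(peptide_len = 15, db_residues = 15e4,
                                alpha = 0.05) {
  ceiling(log(KA_K * peptide_len * db_residues / alpha) / KA_LAMBDA)
}

#' Search a uORF database for conserved uPEP candidates
#'
#' Each query uORF peptide is aligned locally (Smith-Waterman, BLOSUM62,
#' gap open 11 / extend 1) against every peptide in the database —
#' amino-acid-level comparison of the extracted uORF frames, which
#' preferences uPEPs conserved at the peptide rather than nucleotide level.
#' Hits scoring at least `min_score` are returned sorted most conserved
#' first, each carrying the reference transcript pairing needed by the
#' heatmap and Ka/Ks stages.
#'
#' @param query A [transcript()].
#' @param db A `uorf_db`.
#' @param p [uorf_search_params()] used to extract query uORFs.
#' @param min_score Raw-score reporting threshold; default from
#'   [calibrate_min_score()].
#' @return Data frame of hits: query uORF coordinates and peptide, reference
#'   accession/coordinates/peptide, gapped peptide alignment, `raw_score`,
#'   `bit_score`, `evalue` (Karlin-Altschul expectation given database
#'   size), sorted by decreasing `raw_score`.
#' @export
search_conserved <- function(query, db, p = uorf_search_params(),
                             min_score = calibrate_min_score()) {
  stopifnot(inherits(query, "transcript"), inherits(db, "uorf_db"))
  if (!nrow(db$records)) stop("database holds no uORF records", call. = FALSE)
  qu <- find_uorfs(query, p)
  if (!nrow(qu)) {
    message("query '", query$accession, "' contains no qualifying uORF")
    return(empty_hit_frame())
  }
  subj <- Biostrings::AAStringSet(db$records$peptide)
  n_db <- sum(nchar(db$records$peptide))
  hits <- list()
  for (i in seq_len(nrow(qu))) {
    pep <- qu$peptide[i]
    pa <- Biostrings::pairwiseAlignment(
      subj, Biostrings::AAString(pep), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(pa)
    keep <- which(sc >= min_score)
    if (!length(keep)) next
    pak <- Biostrings::pairwiseAlignment(
      subj[keep], Biostrings::AAString(pep), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    hits[[length(hits) + 1L]] <- data.frame(
      query_accession = query$accession,
      query_start = qu$start[i], query_end = qu$end[i],
      query_peptide = pep,
      ref_accession = db$records$accession[keep],
      ref_start = db$records$start[keep], ref_end = db$records$end[keep],
      ref_peptide = db$records$peptide[keep],
      ref_aln = as.character(Biostrings::alignedPattern(pak)),
      query_aln = as.character(Biostrings::alignedSubject(pak)),
      raw_score = sc[keep],
      bit_score = (KA_LAMBDA * sc[keep] - log(KA_K)) / log(2),
      evalue = KA_K * nchar(pep) * n_db * exp(-KA_LAMBDA * sc[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty_hit_frame())
  out <- do.call(rbind, c(hits, make.row.names = FALSE))
  out[order(-out$raw_score, out$evalue, out$ref_accession, out$ref_start), ,
      drop = FALSE]
}

empty_hit_frame <- function() {
  data.frame(query_accession = character(0), query_start = integer(0),
             query_end = integer(0), query_peptide = character(0),
             ref_accession = character(0), ref_start = integer(0),
             ref_end = integer(0), ref_peptide = character(0),
             ref_aln = character(0), query_aln = character(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}
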
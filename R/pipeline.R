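#' End-to-end run configuration
#'
#' Bundles the user-selectable settings of the whole pipeline: alignment
#' scores (defaults +5 match, -4 mismatch, gap open 50, no gap extension),
#' uORF search parameters, the identity-profile window, the translated
#' search threshold, the reciprocal-heatmap toggle and the Ka/Ks method.
#'
#' @param scoring A [scoring_params()].
#' @param uorf A [uorf_search_params()].
#' @param window Odd identity-profile window (nt).
#' @param min_score Raw-score threshold for [search_conserved()].
#' @param reciprocal_heatmap Draw the reference-as-query strip below the
#'   query strip.
#' @param kaks_method `"YN00"` or `"NG86"`.
#' @param seed Seed for any stochastic harness around the pipeline; the
#'   pipeline itself is deterministic.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scoring = scoring_params(), uorf = uorf_search_params(),
                       window = 21L, min_score = calibrate_min_score(),
                       reciprocal_heatmap = TRUE,
                       kaks_method = c("YN00", "NG86"), seed = 1L) {
  stopifnot(inherits(scoring, "scoring_params"),
            inherits(uorf, "uorf_search_params"))
  structure(list(scoring = scoring, uorf = uorf, window = as.integer(window),
                 min_score = min_score,
                 reciprocal_heatmap = isTRUE(reciprocal_heatmap),
                 kaks_method = match.arg(kaks_method),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror [run_config()]: `match`, `mismatch`, `gap_open`,
#' `gap_extend`, `min_len_codons`, `max_overlap_nt`, `search_limit_nt`,
#' `window`, `min_score`, `reciprocal_heatmap`, `kaks_method`, `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(key, default) y[[key]] %||% default
  run_config(
    scoring = scoring_params(g("match", 5), g("mismatch", -4),
                             g("gap_open", 50), g("gap_extend", 0)),
    uorf = uorf_search_params(g("min_len_codons", 10), g("max_overlap_nt", 0),
                              y[["search_limit_nt"]]),
    window = g("window", 21), min_score = g("min_score", calibrate_min_score()),
    reciprocal_heatmap = g("reciprocal_heatmap", TRUE),
    kaks_method = g("kaks_method", "YN00"), seed = g("seed", 1))
}

#' Run the full conserved-uPEP search pipeline
#'
#' Reproduces the end-to-end flow: query uORF extraction, translated search
#' against the database, then per hit a global mRNA alignment, identity
#' profile(s), an annotated heatmap, and uORF + mORF Ka/Ks. Artefacts are
#' written to per-hit subdirectories named by reference accession, plus a
#' `summary.tsv` sorted most-conserved-first. A failing stage is recorded in
#' the summary's `error` column and does not abort the remaining hits. The
#' run is fully deterministic given inputs and configuration.
#'
#' @param query A [transcript()].
#' @param db A `uorf_db` from [build_uorf_db()].
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return (Invisibly) the summary data frame.
#' @export
run_conserved_upep_search <- function(query, db, cfg = run_config(), out_dir) {
  stopifnot(inherits(query, "transcript"), inherits(db, "uorf_db"),
            inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- search_conserved(query, db, cfg$uorf, cfg$min_score)
  summary_rows <- list()
  if (nrow(hits)) for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    hit_dir <- file.path(out_dir, sprintf("%02d_%s", i, h$ref_accession))
    dir.create(hit_dir, showWarnings = FALSE)
    row <- data.frame(rank = i, h,
                      uorf_kaks = NA_real_, morf_kaks = NA_real_,
                      error = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      ref <- db$transcripts[[h$ref_accession]]
      a <- global_align(query, ref, cfg$scoring)
      write_alignment_text(a, file.path(hit_dir, "aligned.txt"))
      prof_q <- compute_profile(a, cfg$window, on = "query")
      utils::write.table(profile_table(prof_q),
                         file.path(hit_dir, "profile.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      profs <- list(prof_q)
      feats_q <- list(list("uORF", orf_interval(h$query_start, h$query_end)),
                      list("mORF", find_morf(query)))
      feats <- list(feats_q)
      if (cfg$reciprocal_heatmap) {
        profs[[2]] <- compute_profile(a, cfg$window, on = "reference")
        feats[[2]] <- list(list("uORF", orf_interval(h$ref_start, h$ref_end)),
                           list("mORF", find_morf(ref)))
      }
      render_heatmap(profs, feats, out = file.path(hit_dir, "heatmap.png"))
      rep <- compare_uorf_morf(query, ref, h, method = cfg$kaks_method,
                               alignment = a)
      utils::write.table(kaks_table(rep), file.path(hit_dir, "kaks.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(uorf = if (inherits(rep$uorf, "kaks_result")) rep$uorf$ratio
           else NA_real_,
           morf = if (inherits(rep$morf, "kaks_result")) rep$morf$ratio
           else NA_real_)
    }, error = function(e) e)
    if (inherits(res, "error")) row$error <- conditionMessage(res)
    else { row$uorf_kaks <- res$uorf; row$morf_kaks <- res$morf }
    summary_rows[[i]] <- row
  }
  summary <- if (length(summary_rows))
    do.call(rbind, c(summary_rows, make.row.names = FALSE))
  else cbind(data.frame(rank = integer(0)), empty_hit_frame(),
             data.frame(uorf_kaks = numeric(0), morf_kaks = numeric(0),
                        error = character(0)))
  summary$ref_aln <- NULL; summary$query_aln <- NULL
  utils::write.table(format(summary, digits = 6),
                     file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!nrow(summary))
    message("no conserved uORF hit at threshold ", cfg$min_score)
  invisible(summary)
}

#' Align two transcripts and render their identity heatmap
#'
#' The direct entry into the heatmap stage: accepts two sequences, aligns
#' them globally, computes the windowed identity profile (and the
#' reciprocal profile when enabled), annotates ORF bars from CDS
#' annotation or de novo mORF/uORF finding, and writes the heatmap PNG and
#' a TSV dump of the profile.
#'
#' @param q,r [transcript()] objects (or nucleotide strings).
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return (Invisibly) list with the alignment, profiles and heatmap
#'   layout.
#' @export
run_heatmap_only <- function(q, r, cfg = run_config(), out_dir) {
  if (!inherits(q, "transcript")) q <- transcript("query", q)
  if (!inherits(r, "transcript")) r <- transcript("reference", r)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- global_align(q, r, cfg$scoring)
  write_alignment_text(a, file.path(out_dir, "aligned.txt"))
  prof_q <- compute_profile(a, cfg$window, on = "query")
  utils::write.table(profile_table(prof_q), file.path(out_dir, "profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  annot <- function(t) {
    feats <- list()
    morf <- tryCatch(find_morf(t), error = function(e) NULL)
    if (!is.null(morf)) {
      feats[[1]] <- list("mORF", morf)
      u <- tryCatch(find_uorfs(t, cfg$uorf), error = function(e) NULL)
      if (!is.null(u) && nrow(u))
        for (k in seq_len(nrow(u)))
          feats[[length(feats) + 1L]] <-
            list("uORF", orf_interval(u$start[k], u$end[k]))
    }
    feats
  }
  profs <- list(prof_q)
  feats <- list(annot(q))
  if (cfg$reciprocal_heatmap) {
    profs[[2]] <- compute_profile(a, cfg$window, on = "reference")
    feats[[2]] <- annot(r)
  }
  layout <- render_heatmap(profs, feats, out = file.path(out_dir, "heatmap.png"))
  invisible(list(alignment = a, profiles = profs, layout = layout))
}
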
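# --- codon machinery -------------------------------------------------------

NT <- c("T", "C", "A", "G")

all_codons <- function() {
  as.vector(outer(outer(NT, NT, paste0), NT, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

codon_aa <- function(codon) {
  gc <- codon_table()
  unname(gc[codon])
}

is_transition <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
    (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}

# package-local caches for per-codon site counts and per-pair path counts
.kaks_cache <- new.env(parent = emptyenv())

# NG86 site counting for one codon: at each position the three alternative
# bases are classified; changes to stop codons are excluded and the position
# renormalised so that every position contributes exactly one site, giving
# S + N = 3 per codon.
ng86_codon_sites <- function(codon) {
  key <- paste0("sites_", codon)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  gc <- codon_table()
  aa0 <- gc[codon]
  s_total <- 0
  for (pos in 1:3) {
    b0 <- substr(codon, pos, pos)
    n_syn <- 0L; n_ok <- 0L
    for (b in setdiff(NT, b0)) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (alt %in% STOP_CODONS) next
      n_ok <- n_ok + 1L
      if (gc[alt] == aa0) n_syn <- n_syn + 1L
    }
    if (n_ok > 0L) s_total <- s_total + n_syn / n_ok
  }
  .kaks_cache[[key]] <- s_total
  s_total
}

# Pathway-averaged difference counts between two sense codons. All shortest
# mutational pathways (permutations of the differing positions) are walked;
# pathways passing through a stop codon are excluded from the average (if
# every pathway is blocked, all are used with steps into/out of stops counted
# as non-synonymous). Each step is classified synonymous/non-synonymous and
# transition/transversion, so the same counts serve NG86 and YN00.
codon_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0, sdts = 0, sdtv = 0, ndts = 0, ndtv = 0))
  key <- paste0("path_", c1, "_", c2)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  gc <- codon_table()
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- permutations_of(diffpos)
  tally <- function(skip_stops) {
    acc <- c(sd = 0, nd = 0, sdts = 0, sdtv = 0, ndts = 0, ndtv = 0)
    n_used <- 0L
    for (ord in perms) {
      cur <- c1
      steps <- matrix(0, nrow = length(ord), ncol = 6)
      blocked <- FALSE
      for (si in seq_along(ord)) {
        pos <- ord[si]
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (skip_stops && nxt %in% STOP_CODONS && si < length(ord)) {
          blocked <- TRUE; break
        }
        aa_cur <- if (cur %in% STOP_CODONS) "*" else gc[cur]
        aa_nxt <- if (nxt %in% STOP_CODONS) "*" else gc[nxt]
        syn <- identical(unname(aa_cur), unname(aa_nxt))
        ts <- is_transition(substr(cur, pos, pos), substr(nxt, pos, pos))
        steps[si, ] <- c(syn, !syn, syn && ts, syn && !ts, !syn && ts,
                         !syn && !ts)
        cur <- nxt
      }
      if (blocked) next
      acc <- acc + colSums(steps)
      n_used <- n_used + 1L
    }
    if (n_used == 0L) return(NULL)
    acc / n_used
  }
  out <- tally(skip_stops = TRUE)
  if (is.null(out)) out <- tally(skip_stops = FALSE)
  names(out) <- c("sd", "nd", "sdts", "sdtv", "ndts", "ndtv")
  .kaks_cache[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# --- codon alignment -------------------------------------------------------

#' Extract a gap- and stop-free codon alignment from a nucleotide alignment
#'
#' Walks the aligned region of the query ORF in query-frame codon steps
#' (excluding the ORF's own terminating stop codon), reads the reference
#' characters at the same alignment columns, and drops every codon column
#' that contains a gap, an N, a stop codon in either sequence, or reference
#' positions outside the reference ORF's coding region.
#'
#' @param a An `alignment_result` over the full (ungapped) sequences.
#' @param q_orf [orf_interval()] of the ORF on the ungapped query.
#' @param r_orf [orf_interval()] of the ORF on the ungapped reference.
#' @return An object of class `codon_alignment`: `q_codons`, `r_codons`
#'   (parallel character vectors), `n_codons`, `dropped_codons`.
#' @export
codon_align <- function(a, q_orf, r_orf) {
  stopifnot(inherits(a, "alignment_result"), inherits(q_orf, "orf_interval"),
            inherits(r_orf, "orf_interval"))
  qc <- strsplit(a$q_aligned, "")[[1]]
  rc <- strsplit(a$r_aligned, "")[[1]]
  idx_q <- which(qc != "-")            # column of each ungapped query position
  rpos <- cumsum(rc != "-")            # ungapped ref position at each column
  q_len <- length(idx_q)
  if (q_orf$end > q_len)
    stop("query ORF lies outside the aligned query", call. = FALSE)
  n_coding <- (q_orf$end - q_orf$start) %/% 3L - 1L
  if (n_coding < 1L)
    stop("insufficient data: query ORF has no coding codon", call. = FALSE)
  r_cod_lo <- r_orf$start + 1L
  r_cod_hi <- r_orf$end - 3L
  q_codons <- character(0); r_codons <- character(0); dropped <- 0L
  for (j in seq_len(n_coding)) {
    ppos <- q_orf$start + 3L * (j - 1L) + (1:3)     # 1-based ungapped query
    cols <- idx_q[ppos]
    qcod <- paste(qc[cols], collapse = "")
    rchars <- rc[cols]
    rcod <- paste(rchars, collapse = "")
    ok <- !any(rchars == "-") &&
      !grepl("N", qcod, fixed = TRUE) && !grepl("N", rcod, fixed = TRUE) &&
      !(qcod %in% STOP_CODONS) && !(rcod %in% STOP_CODONS) &&
      all(rpos[cols] >= r_cod_lo) && all(rpos[cols] <= r_cod_hi)
    if (ok) {
      q_codons <- c(q_codons, qcod); r_codons <- c(r_codons, rcod)
    } else dropped <- dropped + 1L
  }
  if (!length(q_codons))
    stop("insufficient data: no clean codon column after filtering",
         call. = FALSE)
  structure(list(q_codons = q_codons, r_codons = r_codons,
                 n_codons = length(q_codons), dropped_codons = dropped),
            class = "codon_alignment")
}

#' Build a codon alignment directly from two in-frame coding sequences
#'
#' Convenience for simulated or pre-aligned coding sequences of equal
#' length: pairs codons positionally and applies the same stop/ambiguity
#' filter as [codon_align()].
#'
#' @param q_cds,r_cds Equal-length in-frame nucleotide strings.
#' @return A `codon_alignment`.
#' @export
codon_alignment_from_cds <- function(q_cds, r_cds) {
  q_cds <- toupper(q_cds); r_cds <- toupper(r_cds)
  stopifnot(nchar(q_cds) == nchar(r_cds), nchar(q_cds) %% 3L == 0L)
  n <- nchar(q_cds) %/% 3L
  st <- seq(1L, by = 3L, length.out = n)
  qcod <- substring(q_cds, st, st + 2L)
  rcod <- substring(r_cds, st, st + 2L)
  ok <- !(qcod %in% STOP_CODONS) & !(rcod %in% STOP_CODONS) &
    !grepl("N", qcod) & !grepl("N", rcod) &
    !grepl("-", qcod, fixed = TRUE) & !grepl("-", rcod, fixed = TRUE)
  if (!any(ok)) stop("insufficient data: no clean codon column", call. = FALSE)
  structure(list(q_codons = qcod[ok], r_codons = rcod[ok],
                 n_codons = sum(ok), dropped_codons = sum(!ok)),
            class = "codon_alignment")
}

# --- estimators ------------------------------------------------------------

#' Estimate synonymous and non-synonymous substitution rates
#'
#' Two estimators over a gap- and stop-free codon alignment:
#'
#' * **NG86** (Nei-Gojobori 1986): equal-weight site counting per codon
#'   (stop-codon mutations excluded, positions renormalised so S + N equals
#'   three sites per codon), pathway-averaged difference counting for
#'   codons differing at more than one position, and Jukes-Cantor
#'   correction of the proportions pS and pN.
#' * **YN00** (Yang-Nielsen 2000): transition/transversion- and
#'   codon-frequency-weighted site counting (F3x4 codon frequencies
#'   estimated from the data), pathway-averaged difference counts split
#'   into transitions and transversions at synonymous and non-synonymous
#'   sites, and an F84/HKY-style multiple-hit correction applied to each
#'   site class with base frequencies collected at that class. The
#'   transition/transversion ratio kappa is estimated iteratively (start
#'   kappa = 2, convergence |delta kappa| < 1e-6, at most 50 iterations;
#'   non-convergence is flagged and the last iterate reported).
#'
#' Saturation (a multiple-hit correction that diverges) is reported as a
#' flag, not an error; a Ka/Ks ratio with Ks = 0 is flagged undefined and
#' never reported as infinity.
#'
#' @param c A `codon_alignment`.
#' @param method `"YN00"` (default) or `"NG86"`.
#' @return An object of class `kaks_result` with fields `S`, `N`, `Sd`,
#'   `Nd`, `Ka`, `Ks`, `ratio`, `kappa` (NA for NG86), `method`, `flags`.
#' @export
estimate_kaks <- function(c, method = c("YN00", "NG86")) {
  stopifnot(inherits(c, "codon_alignment"))
  method <- match.arg(method)
  if (method == "NG86") estimate_ng86(c) else estimate_yn00(c)
}

new_kaks_result <- function(S, N, Sd, Nd, Ka, Ks, kappa, method, flags) {
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (!is.na(Ks) && Ks == 0) flags <- union(flags, "undefined_ratio")
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, Ka = Ka, Ks = Ks,
                 ratio = ratio, kappa = kappa, method = method,
                 flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> %s: S=%.1f N=%.1f Sd=%.2f Nd=%.2f Ka=%s Ks=%s Ka/Ks=%s%s\n",
    x$method, x$S, x$N, x$Sd, x$Nd, fmt_na(x$Ka), fmt_na(x$Ks),
    fmt_na(x$ratio),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

estimate_ng86 <- function(c) {
  S1 <- sum(vapply(c$q_codons, ng86_codon_sites, 1))
  S2 <- sum(vapply(c$r_codons, ng86_codon_sites, 1))
  S <- (S1 + S2) / 2
  N <- 3 * c$n_codons - S
  diffs <- mapply(function(a, b) codon_path_counts(a, b)[c("sd", "nd")],
                  c$q_codons, c$r_codons)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  flags <- character(0)
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  if (is.na(Ks)) flags <- c(flags, "saturated_ks")
  if (is.na(Ka)) flags <- c(flags, "saturated_ka")
  new_kaks_result(S, N, Sd, Nd, Ka, Ks, NA_real_, "NG86", flags)
}

# F3x4 codon frequencies over the sense codons of both sequences combined.
f3x4_codon_freqs <- function(codons) {
  mat <- do.call(rbind, strsplit(codons, ""))
  fpos <- lapply(1:3, function(j) {
    tab <- table(factor(mat[, j], levels = NT))
    as.numeric(tab) / sum(tab)
  })
  sense <- sense_codons()
  pi <- vapply(sense, function(cod) {
    b <- strsplit(cod, "")[[1]]
    fpos[[1]][match(b[1], NT)] * fpos[[2]][match(b[2], NT)] *
      fpos[[3]][match(b[3], NT)]
  }, 1)
  pi / sum(pi)
}

# kappa- and frequency-weighted site counting for one codon; returns the
# synonymous site count (of 3) plus base-frequency tallies at synonymous and
# non-synonymous sites.
yn00_codon_sites <- function(codon, kappa, pi) {
  gc <- codon_table()
  aa0 <- gc[codon]
  s_total <- 0
  fbS <- fbN <- stats::setNames(numeric(4), NT)
  for (pos in 1:3) {
    b0 <- substr(codon, pos, pos)
    w_syn <- 0; w_all <- 0
    for (b in setdiff(NT, b0)) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (alt %in% STOP_CODONS) next
      w <- (if (is_transition(b0, b)) kappa else 1) * pi[[alt]]
      w_all <- w_all + w
      if (gc[alt] == aa0) w_syn <- w_syn + w
    }
    frac <- if (w_all > 0) w_syn / w_all else 0
    s_total <- s_total + frac
    fbS[b0] <- fbS[b0] + frac
    fbN[b0] <- fbN[b0] + (1 - frac)
  }
  list(s = s_total, fbS = fbS, fbN = fbN)
}

# F84 distance for one site class; returns t (subs/site), the F84 kappa
# parameter converted to an HKY kappa, and a saturation flag.
dist_f84 <- function(P, Q, pi) {
  pi <- pi / sum(pi)
  Tf <- pi[["T"]]; Cf <- pi[["C"]]; Af <- pi[["A"]]; Gf <- pi[["G"]]
  eps <- 1e-6
  Tf <- max(Tf, eps); Cf <- max(Cf, eps); Af <- max(Af, eps); Gf <- max(Gf, eps)
  s <- Tf + Cf + Af + Gf; Tf <- Tf/s; Cf <- Cf/s; Af <- Af/s; Gf <- Gf/s
  Y <- Tf + Cf; R <- Af + Gf
  if (P + Q < 1e-12)
    return(list(t = 0, kappa_hky = NA_real_, saturated = FALSE))
  A <- Tf * Cf / Y + Af * Gf / R
  B <- Tf * Cf + Af * Gf
  Cc <- Y * R
  a_arg <- (2 * B + 2 * (Tf * Cf * R / Y + Af * Gf * Y / R) *
              (1 - Q / (2 * Cc)) - P) / (2 * A)
  b_arg <- 1 - Q / (2 * Cc)
  if (a_arg <= 0 || b_arg <= 0) {
    # Degenerate base composition at this site class can defeat the F84
    # correction even far from saturation; retry under equal frequencies
    # (K80) before declaring the distance saturated.
    if (!all(abs(c(Tf, Cf, Af, Gf) - 0.25) < 1e-9))
      return(dist_f84(P, Q, c(T = 0.25, C = 0.25, A = 0.25, G = 0.25)))
    return(list(t = NA_real_, kappa_hky = NA_real_, saturated = TRUE))
  }
  a <- -0.5 * log(a_arg)
  b <- -0.5 * log(b_arg)
  k_f84 <- if (b > 1e-10) max(a / b - 1, -0.5) else 48
  # t = 4b(TC(1+k/Y) + AG(1+k/R) + YR) with k = a/b - 1, expanded so the
  # Q = 0 limit (b -> 0, k -> Inf) stays finite
  t <- 4 * b * (B + Cc - A) + 4 * a * A
  kappa_hky <- 1 + k_f84 * (Tf * Cf / Y + Af * Gf / R) / B
  list(t = max(t, 0), kappa_hky = min(max(kappa_hky, 0.1), 99),
       saturated = FALSE)
}

estimate_yn00 <- function(c, kappa_init = 2, tol = 1e-6, max_iter = 50L) {
  pi <- f3x4_codon_freqs(c(c$q_codons, c$r_codons))
  diffs <- mapply(codon_path_counts, c$q_codons, c$r_codons)
  Sdts <- sum(diffs["sdts", ]); Sdtv <- sum(diffs["sdtv", ])
  Ndts <- sum(diffs["ndts", ]); Ndtv <- sum(diffs["ndtv", ])
  Sd <- Sdts + Sdtv; Nd <- Ndts + Ndtv
  flags <- character(0)
  kappa <- kappa_init
  converged <- FALSE
  S <- N <- NA_real_; fbS <- fbN <- NULL
  ds <- dn <- list(t = NA_real_, saturated = FALSE)
  for (it in seq_len(max_iter)) {
    counts <- lapply(c(c$q_codons, c$r_codons), yn00_codon_sites,
                     kappa = kappa, pi = pi)
    S <- sum(vapply(counts, `[[`, 1, "s")) / 2
    N <- 3 * c$n_codons - S
    fbS <- Reduce(`+`, lapply(counts, `[[`, "fbS"))
    fbN <- Reduce(`+`, lapply(counts, `[[`, "fbN"))
    ds <- dist_f84(Sdts / S, Sdtv / S, fbS)
    dn <- dist_f84(Ndts / N, Ndtv / N, fbN)
    k_parts <- c(ds$kappa_hky, dn$kappa_hky)
    wts <- c(S, N)[!is.na(k_parts)]
    k_parts <- k_parts[!is.na(k_parts)]
    kappa_new <- if (length(k_parts)) sum(k_parts * wts) / sum(wts) else kappa
    if (abs(kappa_new - kappa) < tol) {
      kappa <- kappa_new; converged <- TRUE; break
    }
    kappa <- kappa_new
  }
  if (!converged) flags <- c(flags, "kappa_nonconvergence")
  if (ds$saturated) flags <- c(flags, "saturated_ks")
  if (dn$saturated) flags <- c(flags, "saturated_ka")
  new_kaks_result(S, N, Sd, Nd, dn$t, ds$t, kappa, "YN00", flags)
}

# --- paired uORF vs mORF report -------------------------------------------

#' Compare selective pressure on a uORF against the mORF internal control
#'
#' Aligns the two transcripts globally, builds codon alignments for the
#' uORF pair and for the mORF pair from the same alignment, and estimates
#' Ka/Ks for both regions. Because synonymous substitutions are favoured in
#' protein-coding sequence, the mORF ratio serves as an internal control:
#' a uORF ratio at or below it supports a functional encoded peptide.
#'
#' @param query,ref [transcript()] objects.
#' @param uorf_pair Either a one-row hit from [search_conserved()] or a
#'   `list(query = orf_interval, ref = orf_interval)`.
#' @param method `"YN00"` or `"NG86"`.
#' @param scoring [scoring_params()] for the transcript alignment.
#' @param alignment Optional precomputed `alignment_result` of query vs ref.
#' @return An object of class `uorf_morf_report`: `uorf` and `morf`
#'   (`kaks_result` or an error flag for the failing side), and
#'   `ratio_of_ratios` (uORF ratio / mORF ratio; NA when either side is
#'   undefined).
#' @export
compare_uorf_morf <- function(query, ref, uorf_pair, method = c("YN00", "NG86"),
                              scoring = scoring_params(), alignment = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(query, "transcript"), inherits(ref, "transcript"))
  if (is.data.frame(uorf_pair)) {
    stopifnot(nrow(uorf_pair) == 1L)
    uorf_pair <- list(query = orf_interval(uorf_pair$query_start,
                                           uorf_pair$query_end),
                      ref = orf_interval(uorf_pair$ref_start,
                                         uorf_pair$ref_end))
  }
  a <- alignment %||% global_align(query, ref, scoring)
  side <- function(q_orf, r_orf) {
    tryCatch(estimate_kaks(codon_align(a, q_orf, r_orf), method),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "kaks_failure"))
  }
  uorf_res <- side(uorf_pair$query, uorf_pair$ref)
  morf_res <- side(find_morf(query), find_morf(ref))
  rr <- NA_real_
  if (inherits(uorf_res, "kaks_result") && inherits(morf_res, "kaks_result") &&
      !is.na(uorf_res$ratio) && !is.na(morf_res$ratio) && morf_res$ratio > 0)
    rr <- uorf_res$ratio / morf_res$ratio
  structure(list(uorf = uorf_res, morf = morf_res, ratio_of_ratios = rr,
                 method = method, alignment = a),
            class = "uorf_morf_report")
}

#' @export
print.uorf_morf_report <- function(x, ...) {
  cat("<uorf_morf_report> method:", x$method, "\n  uORF: ")
  if (inherits(x$uorf, "kaks_result")) print(x$uorf) else
    cat("failed:", x$uorf$error, "\n")
  cat("  mORF: ")
  if (inherits(x$morf, "kaks_result")) print(x$morf) else
    cat("failed:", x$morf$error, "\n")
  cat(sprintf("  ratio of ratios (uORF/mORF): %s\n", fmt_na(x$ratio_of_ratios)))
  invisible(x)
}

#' Flatten a paired report to a TSV-ready table
#'
#' @param report A `uorf_morf_report`.
#' @return Data frame with one row per region (uORF, mORF) and columns
#'   region, S, N, Sd, Nd, Ka, Ks, ratio, kappa, flags.
#' @export
kaks_table <- function(report) {
  stopifnot(inherits(report, "uorf_morf_report"))
  row <- function(region, r) {
    if (inherits(r, "kaks_result"))
      data.frame(region = region, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
                 Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, kappa = r$kappa,
                 flags = paste(r$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(region = region, S = NA_real_, N = NA_real_, Sd = NA_real_,
                 Nd = NA_real_, Ka = NA_real_, Ks = NA_real_,
                 ratio = NA_real_, kappa = NA_real_,
                 flags = paste0("failed:", r$error), stringsAsFactors = FALSE)
  }
  rbind(row("uORF", report$uorf), row("mORF", report$morf))
}
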
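# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic transcript generator
#'
#' Describes an mRNA pair with planted, parameterised conservation
#' structure: a query transcript (random UTRs, random-codon CDS, planted
#' uORFs) and a reference derived from it by mutation. Amino-acid
#' conservation of the planted uORFs is controlled directly by
#' `uorf_identity_aa` when it is not `NA`; otherwise uORF codons evolve
#' under the same synonymy-acceptance model as the CDS with `omega_uorf`.
#'
#' @param seed Integer seed; the pair is fully reproducible from it.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param cds_len_codons CDS length in codons, start and stop included.
#' @param n_uorfs Number of planted uORFs.
#' @param uorf_len_codons Planted uORF length in coding codons (stop
#'   excluded; the encoded peptide has this many residues).
#' @param uorf_identity_aa Target amino-acid identity of planted uORFs
#'   between query and reference, or `NA` to use the omega model.
#' @param background_identity_nt Expected per-nucleotide identity of the
#'   UTR background, and the per-site mutation pressure applied to coding
#'   regions before synonymy acceptance.
#' @param omega_uorf,omega_morf Acceptance probability of non-synonymous
#'   proposals in the uORF (when `uorf_identity_aa` is `NA`) and CDS;
#'   `omega = 0` yields purely synonymous coding divergence.
#' @param indel_rate Per-site probability of opening a short (1-3 nt) indel
#'   in non-coding regions of the reference.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, utr5_len = 300L, cds_len_codons = 200L,
                         utr3_len = 200L, n_uorfs = 1L,
                         uorf_len_codons = 25L, uorf_identity_aa = 0.6,
                         background_identity_nt = 0.6, omega_uorf = 0.1,
                         omega_morf = 0.2, indel_rate = 0.02) {
  s <- list(seed = as.integer(seed), utr5_len = as.integer(utr5_len),
            cds_len_codons = as.integer(cds_len_codons),
            utr3_len = as.integer(utr3_len), n_uorfs = as.integer(n_uorfs),
            uorf_len_codons = as.integer(uorf_len_codons),
            uorf_identity_aa = uorf_identity_aa,
            background_identity_nt = background_identity_nt,
            omega_uorf = omega_uorf, omega_morf = omega_morf,
            indel_rate = indel_rate)
  probs <- c(s$background_identity_nt, s$omega_uorf, s$omega_morf,
             s$indel_rate, if (!is.na(s$uorf_identity_aa)) s$uorf_identity_aa)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (s$utr5_len < 1L || s$utr3_len < 0L || s$cds_len_codons < 3L ||
      s$uorf_len_codons < 1L || s$n_uorfs < 0L)
    stop("lengths must be positive", call. = FALSE)
  span <- 3L * (s$uorf_len_codons + 1L)
  if (s$n_uorfs > 0L && s$n_uorfs * (span + 2L) > s$utr5_len)
    stop(sprintf("infeasible geometry: %d uORF(s) of %d nt do not fit a %d nt 5'UTR",
                 s$n_uorfs, span, s$utr5_len), call. = FALSE)
  structure(s, class = "fixture_spec")
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# transition-biased substitute for one base (kappa = 2: transition chosen
# with probability kappa / (kappa + 2))
mutate_base <- function(b, kappa = 2) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < kappa / (kappa + 2)) ts[[b]]
  else sample(setdiff(setdiff(c("A", "C", "G", "T"), b), ts[[b]]), 1L)
}

random_sense_codon <- function(n, exclude_atg = TRUE) {
  pool <- sense_codons()
  if (exclude_atg) pool <- setdiff(pool, "ATG")
  sample(pool, n, replace = TRUE)
}

# --- query construction ----------------------------------------------------

# Build one transcript: UTRs, CDS, planted uORFs; returns transcript + truth.
# Assumes an active RNG state (callers wrap in with_seed).
build_query <- function(spec, accession, species = "query organism") {
  utr5 <- random_bases(spec$utr5_len)
  cds <- c("ATG", random_sense_codon(spec$cds_len_codons - 2L,
                                     exclude_atg = FALSE),
           sample(STOP_CODONS, 1L))
  utr3 <- random_bases(spec$utr3_len)
  span <- 3L * (spec$uorf_len_codons + 1L)
  uorf_starts <- integer(0)
  if (spec$n_uorfs > 0L) {
    slot <- spec$utr5_len %/% spec$n_uorfs
    offs <- sample.int(max(slot - span, 1L), spec$n_uorfs, replace = TRUE) - 1L
    uorf_starts <- (seq_len(spec$n_uorfs) - 1L) * slot + offs
    uorf_starts <- pmin(uorf_starts, spec$utr5_len - span)
  }
  for (s in uorf_starts) {
    codons <- c("ATG", random_sense_codon(spec$uorf_len_codons - 1L),
                sample(STOP_CODONS, 1L))
    substr_assign <- paste(codons, collapse = "")
    utr5[(s + 1L):(s + span)] <- strsplit(substr_assign, "")[[1]]
  }
  seqchars <- c(utr5, strsplit(paste(cds, collapse = ""), "")[[1]], utr3)
  morf_start <- spec$utr5_len
  seqchars <- fix_stray_atgs(seqchars, morf_start, uorf_starts, span)
  seq <- paste(seqchars, collapse = "")
  t <- transcript(accession, seq,
                  cds = orf_interval(morf_start,
                                     morf_start + 3L * spec$cds_len_codons),
                  species = species)
  truth <- data.frame(
    accession = accession, start = uorf_starts, end = uorf_starts + span,
    frame = uorf_starts %% 3L, length_codons = spec$uorf_len_codons,
    overlap_nt = 0L,
    peptide = vapply(uorf_starts, function(s)
      translate_nt(substr(seq, s + 1L, s + span - 3L)), ""),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(transcript = t, uorfs = truth)
}

# Remove every ATG 5' of the mORF start that is not a planted uORF start,
# by a minimal deterministic single-base edit that never touches the mORF,
# a planted start/stop codon, or creates an in-frame stop inside a planted
# uORF. Bounded rescan loop; errors if the sequence cannot be sanitised.
fix_stray_atgs <- function(seqchars, morf_start, uorf_starts, span) {
  in_uorf <- function(pos) {    # 0-based position; which uORF covers it
    for (s in uorf_starts) if (pos >= s && pos < s + span) return(s)
    NA_integer_
  }
  for (iter in 1:300) {
    seq <- paste(seqchars, collapse = "")
    hits <- atg_positions(seq)
    hits <- hits[hits < morf_start & !(hits %in% uorf_starts)]
    if (!length(hits)) return(seqchars)
    s <- hits[1]
    gc <- codon_table()
    # rank candidate single-base edits: outside coding beats a synonymous
    # in-uORF edit beats a non-synonymous one, so planted codon content is
    # disturbed as little as possible
    best <- NULL; best_rank <- Inf
    for (pos in (s + 2L):s) {             # prefer editing the G, then T, then A
      u <- in_uorf(pos)
      if (!is.na(u)) {
        cod_idx <- (pos - u) %/% 3L       # 0-based codon index within the uORF
        if (cod_idx == 0L || cod_idx == span %/% 3L - 1L) next  # start/stop
      }
      for (b in c("C", "A", "T", "G")) {
        if (b == seqchars[pos + 1L]) next
        cand <- seqchars
        cand[pos + 1L] <- b
        if (paste(cand[(s + 1L):(s + 3L)], collapse = "") == "ATG") next
        rank <- 0
        if (!is.na(u)) {
          cs <- u + 3L * ((pos - u) %/% 3L)
          old_cod <- paste(seqchars[(cs + 1L):(cs + 3L)], collapse = "")
          new_cod <- paste(cand[(cs + 1L):(cs + 3L)], collapse = "")
          if (new_cod %in% STOP_CODONS || new_cod == "ATG") next
          rank <- if (gc[new_cod] == gc[old_cod]) 1 else 2
        }
        rank <- rank * 10 + (pos - s)     # deterministic tie-break
        if (rank < best_rank) { best <- cand; best_rank <- rank }
      }
    }
    if (is.null(best)) stop("cannot sanitise fixture sequence", call. = FALSE)
    seqchars <- best
  }
  stop("cannot sanitise fixture sequence", call. = FALSE)
}

# --- reference derivation --------------------------------------------------

mutate_utr <- function(chars, p_sub, indel_rate) {
  n <- length(chars)
  if (n == 0L) return(chars)
  sub <- stats::runif(n) < p_sub
  for (i in which(sub)) chars[i] <- mutate_base(chars[i])
  if (indel_rate > 0) {
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      r <- stats::runif(1)
      if (r < indel_rate / 2) {                       # deletion of 1-3 nt
        i <- i + sample(1:3, 1L)
      } else if (r < indel_rate) {                    # insertion of 1-3 nt
        out <- c(out, chars[i], random_bases(sample(1:3, 1L)))
        i <- i + 1L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    chars <- out
  }
  chars
}

# Omega-acceptance mutation of an in-frame codon vector (start/stop codons
# untouched): each site receives a proposal with probability p_sub;
# proposals creating stops (or ATG, which would plant a spurious uAUG) are
# rejected; synonymous proposals are always accepted, non-synonymous ones
# with probability omega.
mutate_coding <- function(codons, p_sub, omega, protect = c(1L, length(codons))) {
  gc <- codon_table()
  for (k in seq_along(codons)) {
    if (k %in% protect) next
    for (pos in 1:3) {
      if (stats::runif(1) >= p_sub) next
      cod <- codons[k]
      b <- substr(cod, pos, pos)
      nb <- mutate_base(b)
      alt <- cod
      substr(alt, pos, pos) <- nb
      if (alt %in% STOP_CODONS || alt == "ATG") next
      if (gc[alt] == gc[cod] || stats::runif(1) < omega) codons[k] <- alt
    }
  }
  codons
}

# Mutate a planted uORF to an exact amino-acid identity target: plant
# round((1 - target) * n) non-synonymous single-nucleotide changes at
# distinct codons (never the start Met), plus synonymous changes elsewhere
# at rate p_syn.
mutate_uorf_to_identity <- function(codons, identity_aa, p_syn) {
  gc <- codon_table()
  n <- length(codons) - 1L                    # coding codons incl. start Met
  stopifnot(codons[1] == "ATG", codons[n + 1L] %in% STOP_CODONS)
  k_nonsyn <- round((1 - identity_aa) * n)
  k_nonsyn <- min(k_nonsyn, n - 1L)
  targets <- if (k_nonsyn > 0L) sample(2:n, k_nonsyn) else integer(0)
  for (k in seq_len(n)[-1]) {
    cod <- codons[k]
    if (k %in% targets) {
      cands <- single_nt_neighbours(cod)
      cands <- cands[!(cands %in% STOP_CODONS) & cands != "ATG" &
                       gc[cands] != gc[cod]]
      if (length(cands)) codons[k] <- sample(cands, 1L)
    } else if (stats::runif(1) < p_syn) {
      cands <- single_nt_neighbours(cod)
      cands <- cands[!(cands %in% STOP_CODONS) & cands != "ATG" &
                       gc[cands] == gc[cod]]
      if (length(cands)) codons[k] <- sample(cands, 1L)
    }
  }
  codons
}

single_nt_neighbours <- function(cod) {
  out <- character(0)
  for (pos in 1:3)
    for (b in setdiff(NT, substr(cod, pos, pos))) {
      alt <- cod
      substr(alt, pos, pos) <- b
      out <- c(out, alt)
    }
  out
}

#' Generate a query/reference transcript pair with planted conservation
#'
#' Builds the query (random UTRs, random-codon CDS, planted uORFs in the
#' 5'UTR), then derives the reference by mutating the UTR background to
#' `background_identity_nt`, mutating uORF and CDS codons under the
#' synonymy-acceptance model (or to the exact `uorf_identity_aa` target),
#' and opening short indels in non-coding regions. Stray upstream AUGs are
#' edited out of both sequences so the planted uORFs are exactly the
#' qualifying set. Fully reproducible from `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `query` and `ref` ([transcript()] objects, CDS
#'   annotated) and `truth`: planted uORF coordinates and peptides on both
#'   sequences plus the generating parameters.
#' @export
make_transcript_pair <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    q <- build_query(spec, "SYNQ_000001", species = "synthetic query")
    span <- 3L * (spec$uorf_len_codons + 1L)
    p_sub <- 1 - spec$background_identity_nt
    qseq <- strsplit(q$transcript$sequence, "")[[1]]
    morf_start <- spec$utr5_len

    # segment the query: UTR pieces between uORFs, uORF spans, CDS, 3'UTR
    bounds <- sort(q$uorfs$start)
    segs <- list(); cur <- 0L
    for (s in bounds) {
      if (s > cur) segs[[length(segs) + 1L]] <-
          list(type = "utr", from = cur, to = s)
      segs[[length(segs) + 1L]] <- list(type = "uorf", from = s, to = s + span)
      cur <- s + span
    }
    if (morf_start > cur)
      segs[[length(segs) + 1L]] <- list(type = "utr", from = cur,
                                        to = morf_start)
    segs[[length(segs) + 1L]] <- list(type = "cds", from = morf_start,
                                      to = morf_start + 3L * spec$cds_len_codons)
    if (spec$utr3_len > 0L)
      segs[[length(segs) + 1L]] <- list(type = "utr",
                                        from = morf_start + 3L * spec$cds_len_codons,
                                        to = length(qseq))

    out <- character(0)
    ref_uorf_starts <- integer(0)
    ref_cds_start <- NA_integer_
    for (sg in segs) {
      piece <- qseq[(sg$from + 1L):sg$to]
      if (sg$type == "utr") {
        piece <- mutate_utr(piece, p_sub, spec$indel_rate)
      } else if (sg$type == "uorf") {
        ref_uorf_starts <- c(ref_uorf_starts, length(out))
        codons <- substring(paste(piece, collapse = ""),
                            seq(1L, span, 3L), seq(3L, span, 3L))
        codons <- if (!is.na(spec$uorf_identity_aa))
          mutate_uorf_to_identity(codons, spec$uorf_identity_aa, p_sub)
        else mutate_coding(codons, p_sub, spec$omega_uorf)
        piece <- strsplit(paste(codons, collapse = ""), "")[[1]]
      } else {
        ref_cds_start <- length(out)
        ncd <- length(piece) %/% 3L
        codons <- substring(paste(piece, collapse = ""),
                            seq(1L, length(piece), 3L),
                            seq(3L, length(piece), 3L))
        codons <- mutate_coding(codons, p_sub, spec$omega_morf)
        piece <- strsplit(paste(codons, collapse = ""), "")[[1]]
      }
      out <- c(out, piece)
    }
    out <- fix_stray_atgs(out, ref_cds_start, ref_uorf_starts, span)
    ref_seq <- paste(out, collapse = "")
    ref <- transcript("SYNR_000001", ref_seq,
                      cds = orf_interval(ref_cds_start,
                                         ref_cds_start + 3L * spec$cds_len_codons),
                      species = "synthetic reference")
    truth <- list(
      query_uorfs = q$uorfs,
      ref_uorfs = data.frame(
        accession = "SYNR_000001", start = ref_uorf_starts,
        end = ref_uorf_starts + span, frame = ref_uorf_starts %% 3L,
        length_codons = spec$uorf_len_codons, overlap_nt = 0L,
        peptide = vapply(ref_uorf_starts, function(s)
          translate_nt(substr(ref_seq, s + 1L, s + span - 3L)), ""),
        stringsAsFactors = FALSE),
      spec = spec)
    list(query = q$transcript, ref = ref, truth = truth)
  })
}

#' Generate a reference transcript set for database building
#'
#' Produces `n` decoy transcripts (each with its own random uORF content
#' under `spec`'s geometry) plus any supplied planted homologue carriers,
#' with a stated fraction of the decoys emitted as mORF-start-undefined
#' records to exercise the database exclusion rule.
#'
#' @param n Number of decoy transcripts.
#' @param spec A [fixture_spec()]; decoy i uses seed `spec$seed * 1000 + i`.
#' @param planted Optional list of [transcript()] carriers (e.g. the `ref`
#'   from [make_transcript_pair()]) appended to the set.
#' @param frac_undefined Fraction of decoys flagged mORF-undefined.
#' @return List of [transcript()] objects.
#' @export
make_database <- function(n, spec = fixture_spec(), planted = list(),
                          frac_undefined = 0.04) {
  stopifnot(n >= 1L)
  if (inherits(planted, "transcript")) planted <- list(planted)
  decoys <- lapply(seq_len(n), function(i) {
    s2 <- spec
    s2$seed <- spec$seed * 1000L + i
    with_seed(s2$seed,
              build_query(s2, sprintf("SYND_%06d", i),
                          species = "synthetic decoy")$transcript)
  })
  n_flag <- floor(frac_undefined * n)
  if (n_flag > 0L)
    for (i in seq_len(n_flag)) decoys[[i]]$morf_undefined <- TRUE
  out <- c(planted, decoys)
  names(out) <- vapply(out, `[[`, "", "accession")
  out
}

#' Simulate a codon-aligned sequence pair under a known omega
#'
#' Evolves `n_codons` sites under a reversible HKY-type codon substitution
#' model (single-nucleotide changes only, transition bias `kappa`,
#' non-synonymous rate multiplier `omega`, stationary codon frequencies
#' `pi`), placing the two sequences a total distance `t` apart (expected
#' number of nucleotide substitutions per codon). The transition matrix is
#' obtained by spectral decomposition of the rate matrix, so the simulator
#' shares no code with the counting estimators and serves as an
#' independent oracle for parameter recovery.
#'
#' @param n_codons Number of codon sites.
#' @param t Divergence in expected substitutions per codon (both branches
#'   combined).
#' @param omega Non-synonymous/synonymous rate ratio used to generate.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @param pi Stationary distribution over the 61 sense codons.
#' @return A `codon_alignment`.
#' @export
simulate_codon_pair <- function(n_codons, t, omega, kappa = 2, seed = 1L,
                                pi = NULL) {
  codons <- sense_codons()
  ncod <- length(codons)
  if (is.null(pi)) pi <- rep(1 / ncod, ncod)
  stopifnot(length(pi) == ncod, abs(sum(pi) - 1) < 1e-8)
  gc <- codon_table()
  Q <- matrix(0, ncod, ncod, dimnames = list(codons, codons))
  for (i in seq_len(ncod)) {
    ci <- codons[i]
    for (alt in single_nt_neighbours(ci)) {
      j <- match(alt, codons)
      if (is.na(j)) next                       # change into a stop codon
      pos <- which(strsplit(ci, "")[[1]] != strsplit(alt, "")[[1]])
      r <- pi[j]
      if (is_transition(substr(ci, pos, pos), substr(alt, pos, pos)))
        r <- r * kappa
      if (gc[ci] != gc[alt]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-pi * diag(Q))                 # one expected substitution/codon
  # reversible: symmetrise with sqrt(pi) and decompose
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  P_half <- diag(1 / sp) %*% eig$vectors %*%
    diag(exp(eig$values * t / 2)) %*% t(eig$vectors) %*% diag(sp)
  P_half[P_half < 0] <- 0
  P_half <- P_half / rowSums(P_half)
  with_seed(seed, {
    anc <- sample.int(ncod, n_codons, replace = TRUE, prob = pi)
    tip <- function(a) vapply(a, function(i)
      sample.int(ncod, 1L, prob = P_half[i, ]), 1L)
    q_cod <- codons[tip(anc)]
    r_cod <- codons[tip(anc)]
    structure(list(q_codons = q_cod, r_codons = r_cod, n_codons = n_codons,
                   dropped_codons = 0L),
              class = "codon_alignment")
  })
}

#' Write a fixture bundle to disk
#'
#' Emits `query.fasta`, `reference.fasta`, a GenBank file with the CDS
#' annotations, and `truth.json` with the planted uORF coordinates.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair <- make_transcript_pair(spec)
  write_fasta(pair$query, file.path(dir, "query.fasta"))
  write_fasta(pair$ref, file.path(dir, "reference.fasta"))
  write_genbank(list(pair$query, pair$ref), file.path(dir, "pair.gb"))
  jsonlite::write_json(
    list(query_uorfs = pair$truth$query_uorfs,
         ref_uorfs = pair$truth$ref_uorfs,
         spec = unclass(pair$truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
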
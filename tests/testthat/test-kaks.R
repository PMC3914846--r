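sample_sense_codons <- function(n, seed) {
  set.seed(seed)
  sample(uorfscan:::sense_codons(), n, replace = TRUE)
}

test_that("site counting matches the code's degeneracy for repeated Phe", {
  # TTT: only the third-position T->C change is synonymous, so each codon
  # contributes exactly 1/3 synonymous site
  ca <- codon_alignment_from_cds(strrep("TTT", 12), strrep("TTT", 12))
  r <- estimate_kaks(ca, "NG86")
  expect_equal(r$S, 12 / 3)
  expect_equal(r$N, 3 * 12 - 12 / 3)
})

test_that("identical sequences give zero rates and an undefined ratio", {
  cds <- paste(sample_sense_codons(50, seed = 1), collapse = "")
  for (m in c("NG86", "YN00")) {
    r <- estimate_kaks(codon_alignment_from_cds(cds, cds), m)
    expect_equal(r$Ka, 0)
    expect_equal(r$Ks, 0)
    expect_true(is.na(r$ratio))
    expect_true("undefined_ratio" %in% r$flags)
  }
})

test_that("a single synonymous third-position change gives Ka = 0, Ks > 0", {
  q <- paste(rep("GCT", 100), collapse = "")
  r <- paste(c("GCC", rep("GCT", 99)), collapse = "")
  for (m in c("NG86", "YN00")) {
    res <- estimate_kaks(codon_alignment_from_cds(q, r), m)
    expect_equal(res$Nd, 0)
    expect_equal(res$Ka, 0)
    expect_equal(res$Sd, 1)
    expect_gt(res$Ks, 0)
  }
})

test_that("pathway-averaged differences match the enumeration oracle", {
  # all codon pairs differing at 1 position, plus a random sample of
  # multi-position pairs (the full 61x61 grid runs in the acceptance suite)
  sense <- uorfscan:::sense_codons()
  set.seed(12)
  pairs <- expand.grid(a = sense, b = sample(sense, 12),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    got <- uorfscan:::codon_path_counts(pairs$a[i], pairs$b[i])
    exp <- oracle_path_diffs(pairs$a[i], pairs$b[i])
    expect_equal(unname(got["sd"]), unname(exp["sd"]))
    expect_equal(unname(got["nd"]), unname(exp["nd"]))
    expect_equal(got["sd"] + got["nd"],
                 c(sd = sum(strsplit(pairs$a[i], "")[[1]] !=
                              strsplit(pairs$b[i], "")[[1]])))
  }
})

test_that("both estimators are symmetric in their arguments", {
  ca <- simulate_codon_pair(200, t = 0.5, omega = 0.4, seed = 5)
  rev <- structure(list(q_codons = ca$r_codons, r_codons = ca$q_codons,
                        n_codons = ca$n_codons, dropped_codons = 0L),
                   class = "codon_alignment")
  for (m in c("NG86", "YN00")) {
    a <- estimate_kaks(ca, m); b <- estimate_kaks(rev, m)
    expect_equal(a$Ka, b$Ka, tolerance = 1e-9)
    expect_equal(a$Ks, b$Ks, tolerance = 1e-9)
    expect_equal(a$S, b$S, tolerance = 1e-9)
  }
})

test_that("saturation is flagged rather than thrown", {
  set.seed(41)
  ca <- simulate_codon_pair(150, t = 40, omega = 1, seed = 41)
  r <- estimate_kaks(ca, "NG86")
  expect_s3_class(r, "kaks_result")
  expect_true(any(grepl("saturated", r$flags)) || (!is.na(r$Ks) && r$Ks > 1))
})

test_that("codon_align extracts clean codon columns from an alignment", {
  # identical ORFs, gap-free
  pair <- make_transcript_pair(fixture_spec(seed = 6, uorf_identity_aa = 1,
                                            background_identity_nt = 1,
                                            omega_morf = 0, indel_rate = 0))
  a <- global_align(pair$query, pair$ref)
  morf_q <- find_morf(pair$query); morf_r <- find_morf(pair$ref)
  ca <- codon_align(a, morf_q, morf_r)
  expect_equal(ca$n_codons, (morf_q$end - morf_q$start) / 3 - 1)
  expect_equal(ca$dropped_codons, 0)
  expect_identical(ca$q_codons, ca$r_codons)
})

test_that("a gap inside the ORF drops exactly the overlapping codon columns", {
  # reference lost one whole codon: only the gapped query codon is dropped
  a <- uorfscan:::new_alignment_result("ATGGAACTTAGATGA",
                                       "ATG---CTTAGATGA", 0, scoring_params())
  ca <- codon_align(a, orf_interval(0, 15), orf_interval(0, 12))
  expect_equal(ca$dropped_codons, 1)
  expect_equal(ca$n_codons, 3)
  expect_equal(ca$q_codons, c("ATG", "CTT", "AGA"))

  # gap out of phase with the query frame: two codons affected
  b <- uorfscan:::new_alignment_result("ATGGAACTTAGATGA",
                                       "ATGG---TTAGATGA", 0, scoring_params())
  cb <- codon_align(b, orf_interval(0, 15), orf_interval(0, 12))
  expect_equal(cb$dropped_codons, 2)
  expect_equal(cb$n_codons, 2)
})

test_that("an N-containing codon is dropped, the rest retained", {
  q <- strrep("GAC", 20)
  r <- paste0(strrep("GAC", 10), "GNC", strrep("GAC", 9))
  ca <- codon_alignment_from_cds(q, r)
  expect_equal(ca$dropped_codons, 1)
  expect_equal(ca$n_codons, 19)
})

test_that("uORF under synonymous-only evolution beats a neutral mORF", {
  spec <- fixture_spec(seed = 19, uorf_identity_aa = NA, omega_uorf = 0,
                       omega_morf = 1, indel_rate = 0,
                       background_identity_nt = 0.7)
  pair <- make_transcript_pair(spec)
  u <- pair$truth$query_uorfs; ur <- pair$truth$ref_uorfs
  rep <- compare_uorf_morf(pair$query, pair$ref,
                           list(query = orf_interval(u$start[1], u$end[1]),
                                ref = orf_interval(ur$start[1], ur$end[1])),
                           method = "NG86")
  expect_s3_class(rep$uorf, "kaks_result")
  expect_s3_class(rep$morf, "kaks_result")
  expect_equal(rep$uorf$Ka, 0)
  expect_gt(rep$morf$ratio, 0.3)
  expect_true(is.na(rep$uorf$ratio) || rep$uorf$ratio < rep$morf$ratio)
})

test_that("identical transcripts give undefined ratios on both sides", {
  pair <- make_transcript_pair(fixture_spec(seed = 9))
  u <- pair$truth$query_uorfs
  rep <- compare_uorf_morf(pair$query, pair$query,
                           list(query = orf_interval(u$start[1], u$end[1]),
                                ref = orf_interval(u$start[1], u$end[1])))
  expect_true(is.na(rep$uorf$ratio))
  expect_true(is.na(rep$morf$ratio))
  expect_true("undefined_ratio" %in% rep$uorf$flags)
  expect_true(is.na(rep$ratio_of_ratios))
})

test_that("a failing uORF side yields a partial report, mORF still present", {
  # uORF of one coding codon whose reference copy carries an N: every uORF
  # codon column is dropped, the mORF is unaffected
  utr_q <- paste0(strrep("C", 6), "ATGGAATAA", strrep("C", 6))
  utr_r <- paste0(strrep("C", 6), "ATGGNATAA", strrep("C", 6))
  cds <- paste0("ATG", strrep("GAC", 20), "TGA")
  q <- transcript("q", paste0(utr_q, cds), cds = orf_interval(21, 21 + 66))
  r <- transcript("r", paste0(utr_r, cds), cds = orf_interval(21, 21 + 66))
  rep <- compare_uorf_morf(q, r,
                           list(query = orf_interval(6, 15),
                                ref = orf_interval(6, 15)), method = "NG86")
  expect_s3_class(rep$uorf, "kaks_failure")
  expect_s3_class(rep$morf, "kaks_result")
  tab <- kaks_table(rep)
  expect_equal(nrow(tab), 2)
  expect_match(tab$flags[tab$region == "uORF"], "failed")
})

sample_sense_codons <- function(n, seed) {
  set.seed(seed)
  sample(uorfscan:::sense_codons(), n, replace = TRUE)
}
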
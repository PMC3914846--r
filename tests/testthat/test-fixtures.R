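test_that("the generator is deterministic under its seed", {
  p1 <- make_transcript_pair(fixture_spec(seed = 42))
  p2 <- make_transcript_pair(fixture_spec(seed = 42))
  expect_identical(p1$query$sequence, p2$query$sequence)
  expect_identical(p1$ref$sequence, p2$ref$sequence)
  expect_identical(p1$truth, p2$truth)
  p3 <- make_transcript_pair(fixture_spec(seed = 43))
  expect_false(identical(p1$query$sequence, p3$query$sequence))
})

test_that("planted truth agrees exactly with the uORF finder", {
  for (s in c(1, 2, 3)) {
    pair <- make_transcript_pair(fixture_spec(seed = s, n_uorfs = 2,
                                              utr5_len = 400))
    for (side in c("query", "ref")) {
      tr <- pair[[side]]
      truth <- pair$truth[[paste0(side, "_uorfs")]]
      got <- find_uorfs(tr)
      expect_equal(got$start, truth$start)
      expect_equal(got$end, truth$end)
      expect_equal(got$peptide, truth$peptide)
    }
  }
})

test_that("amino-acid identity of planted uORFs tracks its target", {
  ids <- vapply(1:20, function(s) {
    pair <- make_transcript_pair(fixture_spec(seed = s,
                                              uorf_identity_aa = 0.6))
    q <- strsplit(pair$truth$query_uorfs$peptide[1], "")[[1]]
    r <- strsplit(pair$truth$ref_uorfs$peptide[1], "")[[1]]
    mean(q == r)
  }, 1)
  expect_lt(abs(mean(ids) - 0.6), 0.05)
})

test_that("UTR background identity approximates its target", {
  spec <- fixture_spec(seed = 11, uorf_identity_aa = 1,
                       background_identity_nt = 0.5, indel_rate = 0)
  pair <- make_transcript_pair(spec)
  u <- pair$truth$query_uorfs
  # indel-free reference: positions align 1:1; compare 3'UTR (no uORF there)
  q3 <- substr(pair$query$sequence, 901, 1100)
  r3 <- substr(pair$ref$sequence, 901, 1100)
  id <- mean(strsplit(q3, "")[[1]] == strsplit(r3, "")[[1]])
  # binomial sampling bound: 4 sd over 200 sites
  expect_lt(abs(id - 0.5), 4 * sqrt(0.25 / 200))
})

test_that("synonymous-only coding evolution leaves the peptide unchanged", {
  spec <- fixture_spec(seed = 14, uorf_identity_aa = NA, omega_uorf = 0,
                       indel_rate = 0)
  pair <- make_transcript_pair(spec)
  expect_identical(pair$truth$query_uorfs$peptide,
                   pair$truth$ref_uorfs$peptide)
  qc <- substr(pair$query$sequence, pair$truth$query_uorfs$start[1] + 1,
               pair$truth$query_uorfs$end[1] - 3)
  rc <- substr(pair$ref$sequence, pair$truth$ref_uorfs$start[1] + 1,
               pair$truth$ref_uorfs$end[1] - 3)
  expect_false(identical(qc, rc))   # nucleotide changes did happen
})

test_that("infeasible geometry is rejected", {
  expect_error(fixture_spec(utr5_len = 50, n_uorfs = 2, uorf_len_codons = 25),
               "infeasible")
  expect_error(fixture_spec(background_identity_nt = 1.2), "probabilities")
})

test_that("make_database plants carriers and flags the stated fraction", {
  spec <- fixture_spec(seed = 33)
  pair <- make_transcript_pair(spec)
  ts <- make_database(50, spec, planted = pair$ref, frac_undefined = 0.04)
  expect_length(ts, 51)
  expect_equal(sum(vapply(ts, `[[`, TRUE, "morf_undefined")), 2)
  expect_false(ts[[pair$ref$accession]]$morf_undefined)
  # deterministic regeneration
  ts2 <- make_database(50, spec, planted = pair$ref, frac_undefined = 0.04)
  expect_identical(vapply(ts, `[[`, "", "sequence"),
                   vapply(ts2, `[[`, "", "sequence"))
})

test_that("fixture bundles round-trip through FASTA, GenBank and JSON", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 5)
  write_fixtures(spec, d)
  q <- read_fasta(file.path(d, "query.fasta"))[[1]]
  gb <- read_genbank(file.path(d, "pair.gb"))
  pair <- make_transcript_pair(spec)
  expect_equal(q$sequence, pair$query$sequence)
  expect_equal(gb[[1]]$cds, pair$query$cds)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$query_uorfs$start, pair$truth$query_uorfs$start)
})

test_that("the codon simulator hits its divergence and omega targets", {
  # omega = 0 generates no amino-acid changes at all
  ca <- simulate_codon_pair(300, t = 0.4, omega = 0, seed = 2)
  gc <- Biostrings::GENETIC_CODE
  expect_identical(unname(gc[ca$q_codons]), unname(gc[ca$r_codons]))
  expect_false(identical(ca$q_codons, ca$r_codons))
  # observed nucleotide differences per codon near (but below, because of
  # multiple hits) the nominal divergence under neutrality
  ca2 <- simulate_codon_pair(2000, t = 0.3, omega = 1, seed = 3)
  diffs <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    ca2$q_codons, ca2$r_codons)
  expect_gt(mean(diffs), 0.22)
  expect_lt(mean(diffs), 0.31)
  # determinism
  ca3 <- simulate_codon_pair(300, t = 0.4, omega = 0, seed = 2)
  expect_identical(ca$q_codons, ca3$q_codons)
})
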
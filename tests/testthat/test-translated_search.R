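test_that("database building applies the mORF-undefined exclusion rule", {
  spec <- fixture_spec(seed = 31)
  ts <- make_database(10, spec, frac_undefined = 0.2)
  expect_length(ts, 10)
  flagged <- names(ts)[vapply(ts, `[[`, TRUE, "morf_undefined")]
  expect_length(flagged, 2)
  db <- build_uorf_db(ts)
  expect_equal(db$source_meta$n_excluded, 2)
  expect_false(any(db$records$accession %in% flagged))
  expect_false(any(names(db$transcripts) %in% flagged))
})

test_that("a transcript without qualifying uORFs contributes zero records", {
  no_uorf <- transcript("bare", paste0(strrep("C", 30), "ATG",
                                       strrep("GAA", 30), "TGA"),
                        cds = orf_interval(30, 126))
  pair <- make_transcript_pair(fixture_spec(seed = 8))
  db <- build_uorf_db(list(no_uorf, pair$query))
  expect_false("bare" %in% db$records$accession)
  expect_true("bare" %in% names(db$transcripts))
  expect_error(build_uorf_db(list(transcript("f", "ACGT",
                                             morf_undefined = TRUE))),
               "empty database")
})

test_that("database build is deterministic and round-trips through disk", {
  ts <- make_database(8, fixture_spec(seed = 13))
  db1 <- build_uorf_db(ts)
  db2 <- build_uorf_db(ts)
  expect_identical(db1$records, db2$records)
  expect_identical(db1$version_tag, db2$version_tag)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_uorf_db(db1, d1); write_uorf_db(db2, d2)
  for (f in c("peptides.fasta", "transcripts.fasta", "meta.yaml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  back <- read_uorf_db(d1)
  expect_equal(back$records, db1$records)
  expect_equal(back$source_meta$n_excluded, db1$source_meta$n_excluded)
})

test_that("an exact peptide copy is retrieved first with its self score", {
  spec <- fixture_spec(seed = 17, uorf_identity_aa = 1, indel_rate = 0)
  pair <- make_transcript_pair(spec)
  db <- build_uorf_db(make_database(50, spec, planted = pair$ref))
  hits <- search_conserved(pair$query, db)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$ref_accession[1], "SYNR_000001")
  pep <- pair$truth$query_uorfs$peptide[1]
  expect_equal(hits$query_peptide[1], hits$ref_peptide[1])
  self <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep), Biostrings::AAString(pep), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1))
  expect_equal(hits$raw_score[1], self)
})

test_that("self-search returns the self-pair as the top hit", {
  pair <- make_transcript_pair(fixture_spec(seed = 23))
  db <- build_uorf_db(make_database(20, fixture_spec(seed = 23),
                                    planted = pair$query))
  hits <- search_conserved(pair$query, db)
  expect_equal(hits$ref_accession[1], pair$query$accession)
  expect_true(all(diff(hits$raw_score) <= 0))
})

test_that("local peptide scores match the brute-force Smith-Waterman oracle", {
  set.seed(303)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:80) {
    a <- paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    got <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1))
    expect_equal(max(got, 0), oracle_local_score(a, b))
  }
})

test_that("a query without uORFs yields an empty result with a notice", {
  bare <- transcript("bare", paste0(strrep("C", 20), "ATG",
                                    strrep("GAA", 30), "TGA"),
                     cds = orf_interval(20, 116))
  db <- build_uorf_db(make_database(5, fixture_spec(seed = 2)))
  expect_message(hits <- search_conserved(bare, db), "no qualifying uORF")
  expect_equal(nrow(hits), 0)
})

test_that("the default threshold follows the expectation calibration", {
  # smallest S with K * m * n * exp(-lambda * S) < alpha
  s <- calibrate_min_score(15, 15e4, 0.05)
  e_at <- 0.041 * 15 * 15e4 * exp(-0.267 * s)
  e_below <- 0.041 * 15 * 15e4 * exp(-0.267 * (s - 1))
  expect_lt(e_at, 0.05)
  expect_gt(e_below, 0.05)
})
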
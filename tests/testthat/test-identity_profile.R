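fake_alignment <- function(q_aligned, r_aligned) {
  uorfscan:::new_alignment_result(q_aligned, r_aligned, 0, scoring_params())
}

test_that("identical sequences give a profile of ones with length q", {
  set.seed(5)
  for (w in c(3, 9, 21)) {
    s <- rand_dna(60)
    a <- global_align(s, s)
    p <- compute_profile(a, w)
    expect_length(p$values, 60)
    expect_true(all(p$values == 1))
  }
})

test_that("the three-branch formula reproduces the hand-evaluated case", {
  # M = [1,0,1,1,0], w = 3 (z = 1): edge branches normalise by z+i and
  # z+m-i+1, the interior by 2z+1
  a <- fake_alignment("ACGTA", "AGGTC")
  expect_equal(a$match_seq, c(1L, 0L, 1L, 1L, 0L))
  p <- compute_profile(a, 3)
  expect_equal(p$values, c(1/2, 2/3, 2/3, 2/3, 1/2))
})

test_that("profile equals the clipped-window oracle on random alignments", {
  set.seed(77)
  for (i in 1:100) {
    m <- sample(20:80, 1)
    qc <- sample(c("A", "C", "G", "T", "-"), m, replace = TRUE,
                 prob = c(rep(0.225, 4), 0.1))
    rc <- sample(c("A", "C", "G", "T", "-"), m, replace = TRUE,
                 prob = c(rep(0.225, 4), 0.1))
    both <- qc == "-" & rc == "-"
    rc[both] <- "A"
    if (!any(qc != "-")) qc[1] <- "A"
    a <- fake_alignment(paste(qc, collapse = ""), paste(rc, collapse = ""))
    w <- sample(c(3, 5, 21), 1)
    p <- compute_profile(a, w)
    expect_equal(p$values, oracle_profile(a$q_aligned, a$match_seq, w))
    expect_length(p$values, sum(qc != "-"))
    expect_true(all(p$values >= 0 & p$values <= 1))
  }
})

test_that("window validation rejects even or non-positive sizes", {
  a <- fake_alignment("ACGT", "ACGT")
  expect_error(compute_profile(a, 4), "odd")
  expect_error(compute_profile(a, 0), "odd|positive")
  expect_error(compute_profile(a, -3), "odd|positive")
})

test_that("query and reference profiles coincide at full identity", {
  s <- rand_dna(50)
  a <- global_align(s, s)
  pq <- compute_profile(a, 7, on = "query")
  pr <- compute_profile(a, 7, on = "reference")
  expect_equal(pq$values, pr$values)
})

test_that("rendered heatmap cells carry the exact gradient colours", {
  s <- rand_dna(40)
  a <- global_align(s, s)
  p <- compute_profile(a, 5)
  f <- withr::local_tempfile(fileext = ".png")
  layout <- render_heatmap(p, out = f, cell_width = 1, cell_height = 4)
  img <- png::readPNG(f)
  strip <- layout$strips[[1]]$strip_rows
  top <- grDevices::col2rgb(identity_gradient()(1)) / 255
  for (ch in 1:3)
    expect_true(all(abs(img[strip, , ch] - top[ch]) < 1/254))
})

test_that("a planted conserved uORF shows as a high-identity block", {
  spec <- fixture_spec(seed = 21, uorf_identity_aa = 1, indel_rate = 0,
                       background_identity_nt = 0.5)
  pair <- make_transcript_pair(spec)
  a <- global_align(pair$query, pair$ref)
  p <- compute_profile(a, 21)
  u <- pair$truth$query_uorfs
  f <- withr::local_tempfile(fileext = ".png")
  layout <- render_heatmap(p, features = list(list("uORF",
                                                   orf_interval(u$start, u$end))),
                           out = f)
  img <- png::readPNG(f)
  strip_row <- layout$strips[[1]]$strip_rows[1]
  grad <- identity_gradient()
  # rendered colours equal gradient(P) cell by cell
  expected <- grDevices::col2rgb(grad(p$values)) / 255
  for (ch in 1:3)
    expect_true(all(abs(img[strip_row, seq_along(p$values), ch] -
                          expected[ch, ]) < 1/254))
  # the uORF block is markedly more conserved than the UTR background
  inside <- mean(p$values[(u$start + 1):u$end])
  utr_cols <- setdiff(1:spec$utr5_len, (u$start - 20):(u$end + 20))
  outside <- mean(p$values[utr_cols])
  expect_gt(inside, outside + 0.2)
  # ORF bar rendered black over the uORF span
  bar_row <- layout$strips[[1]]$bar_rows[1]
  expect_true(all(img[bar_row, (u$start + 1):u$end, 1] < 1/254))
})

test_that("two profiles render as two strips, query first", {
  pair <- make_transcript_pair(fixture_spec(seed = 4))
  a <- global_align(pair$query, pair$ref)
  pq <- compute_profile(a, 21, on = "query")
  pr <- compute_profile(a, 21, on = "reference")
  f <- withr::local_tempfile(fileext = ".png")
  layout <- render_heatmap(list(pq, pr), out = f)
  expect_length(layout$strips, 2)
  expect_equal(layout$strips[[1]]$q, length(pq$values))
  expect_equal(layout$strips[[2]]$q, length(pr$values))
  img <- png::readPNG(f)
  expect_equal(dim(img)[1], layout$height)
  expect_lt(max(layout$strips[[1]]$strip_rows), min(layout$strips[[2]]$strip_rows))
})

test_that("profile_table is a 1-based position/identity dump of length q", {
  s <- rand_dna(30)
  a <- global_align(s, rand_dna(30))
  tab <- profile_table(compute_profile(a, 5))
  expect_equal(nrow(tab), 30)
  expect_equal(tab$position, 1:30)
})
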
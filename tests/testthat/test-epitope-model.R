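# Pocket-profile scoring, threshold calibration, sequence scanning and
# recognition statistics.

test_that("peptide scoring sums position-specific weights", {
  zero <- pocket_matrix("Z*0001", matrix(0, 9, 20))
  expect_equal(score_peptide(zero, "AAAAAAAAA"), 0)

  w <- matrix(0, 9, 20)
  w[1, 1] <- 1 # position 1, residue A
  one <- pocket_matrix("O*0001", w)
  expect_equal(score_peptide(one, "AAAAAAAAA"), 1)
  expect_equal(score_peptide(one, "CAAAAAAAA"), 0)

  panel <- test_panel(1L, seed = 9L)
  m <- panel$matrices[[1L]]
  peps <- vapply(1:20, function(i) random_aa_seq(9, 100 + i), "")
  for (pep in peps) {
    expect_equal(score_peptide(m, pep), naive_score(m, pep))
  }
})

test_that("invalid peptides are rejected with the offending detail", {
  m <- pocket_matrix("Z*0001", matrix(0, 9, 20))
  expect_error(score_peptide(m, "AAAAAAAAX"), "X")
  expect_error(score_peptide(m, "AAAAAAAAB"), "B")
  expect_error(score_peptide(m, "AAAA"), "length 4")
  expect_error(score_peptide(m, "AAAAAAAAAA"), "length 10")
})

test_that("exact convolution calibration matches its worked cases", {
  zero <- pocket_matrix("Z*0001", matrix(0, 9, 20))
  expect_warning(th <- calibrate_threshold(zero, 10), "degenerate")
  expect_equal(th, 0.1) # smallest positive grid value; nothing recognized

  w <- matrix(0, 9, 20)
  w[1, 1:2] <- 1 # two of twenty residues at position 1 score 1.0
  two <- pocket_matrix("T*0001", w)
  expect_equal(calibrate_threshold(two, 10), 1.0) # tail at 1.0 is 2/20
  # stricter levels cannot admit the 10%-sized class
  expect_equal(calibrate_threshold(two, 9), 1.1)
})

test_that("calibration equals brute-force enumeration on a reduced engine", {
  # 4-letter alphabet, window 3: all 64 peptides enumerable by hand
  for (seed in 1:10) {
    m <- with_local_seed(seed, {
      pocket_matrix("TINY*0001",
                    round(matrix(rnorm(tiny_window * 4, sd = 0.7),
                                 nrow = tiny_window), 1),
                    alphabet = tiny_alphabet, window = tiny_window)
    })
    scores <- all_window_scores(m)
    for (pct in c(2L, 5L, 10L)) {
      th <- suppressWarnings(calibrate_threshold(m, pct))
      frac <- mean(scores >= th - 1e-9)
      expect_lte(frac, pct / 100)
      # no smaller attained score also fits within the percentile
      smaller <- sort(unique(scores[scores < th - 1e-9]), decreasing = TRUE)
      if (length(smaller) > 0L) {
        expect_gt(mean(scores >= smaller[1L] - 1e-9), pct / 100)
      }
    }
  }
})

test_that("convolution threshold agrees with sampled percentiles", {
  for (seed in c(3L, 17L)) {
    panel <- random_panel(1L, seed = seed, percents = 10L)
    m <- panel$matrices[[1L]]
    p_exact <- recognition_probability(m, 10)
    expect_lte(p_exact, 0.10)
    samp <- recognition_histogram(panel, 10, n_samples = 2e5, seed = 1L)
    # sampled hit fraction within Monte-Carlo error of the exact tail
    se <- sqrt(p_exact * (1 - p_exact) / 2e5)
    expect_lt(abs(samp[["1"]] - p_exact), 5 * se + 1e-9)
  }
})

test_that("sequence scanning matches a naive window-by-window rescan", {
  panel <- test_panel(3L, seed = 11L)
  seq9 <- random_aa_seq(9, 21)
  prof9 <- scan_sequence(panel, seq9, 10)
  expect_length(prof9$window_start, 1L)

  seq30 <- random_aa_seq(30, 22)
  prof <- scan_sequence(panel, seq30, 10)
  expect_equal(prof$E, naive_scan_E(panel, seq30, 10))
  expect_equal(prof$E, sum(prof$window_count))
  expect_equal(length(prof$window_start), 30 - 8)

  expect_error(scan_sequence(panel, "AAAA", 10), "at least 9")
  expect_error(scan_sequence(panel, paste0(seq9, "X"), 10), "X")
})

test_that("stricter percent levels never add hits and prefixes decompose", {
  panel <- test_panel(2L, seed = 5L, percents = c(10L, 5L, 2L))
  seq1 <- random_aa_seq(20, 31)
  seq2 <- random_aa_seq(15, 32)
  p10 <- scan_sequence(panel, seq1, 10)
  p5 <- scan_sequence(panel, seq1, 5)
  p2 <- scan_sequence(panel, seq1, 2)
  expect_true(all(p5$window_count <= p10$window_count))
  expect_true(all(p2$window_count <= p5$window_count))

  combined <- scan_sequence(panel, paste0(seq1, seq2), 10)
  inside <- seq_len(nchar(seq1) - 8)
  expect_equal(combined$window_count[inside], p10$window_count)
})

test_that("recognition histogram is a reproducible distribution", {
  zero <- pocket_matrix("Z*0001", matrix(0, 9, 20),
                        thresholds = c("10" = 0.1))
  pz <- allele_panel(list(zero))
  h0 <- recognition_histogram(pz, 10, n_samples = 500, seed = 4L)
  expect_equal(unname(h0[["0"]]), 1)

  panel <- test_panel(3L, seed = 13L)
  h1 <- recognition_histogram(panel, 10, n_samples = 2e4, seed = 7L)
  h2 <- recognition_histogram(panel, 10, n_samples = 2e4, seed = 7L)
  expect_identical(h1, h2)
  expect_equal(sum(h1), 1, tolerance = 1e-12)
  expect_length(h1, length(panel$matrices) + 1L)
})

test_that("matrix set TSV dialect round-trips and rejects bad lines", {
  panel <- test_panel(2L, seed = 19L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_set(panel, path)
  back <- read_matrix_set(path)
  expect_identical(back$alleles, panel$alleles)
  for (a in seq_along(panel$matrices)) {
    expect_identical(back$matrices[[a]]$w10, panel$matrices[[a]]$w10)
    expect_equal(back$matrices[[a]]$thresholds,
                 panel$matrices[[a]]$thresholds)
  }

  lines <- readLines(path)
  lines[2] <- sub("\t", " oops\t", lines[2])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_matrix_set(bad), ":2:")
})
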
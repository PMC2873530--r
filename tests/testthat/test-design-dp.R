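# The suffix-state dynamic program: optimality, budgets, near-optimal
# enumeration, tie-breaking, and agreement with the brute-force oracle.

test_that("a fully pinned map returns the wild type with its scan score", {
  panel <- test_panel(2L, seed = 3L)
  seq <- random_aa_seq(12, 41)
  M <- explicit_allowed(seq, as.list(strsplit(seq, "")[[1]]))
  pr <- design_problem(seq, panel, 10, M)
  best <- optimize_design(pr)
  expect_identical(best$sequence, seq)
  expect_equal(best$total_score, scan_sequence(panel, seq, 10)$E)
})

test_that("budget zero returns the wild type", {
  pr <- random_design_problem(seed = 8L, n = 12L)
  v0 <- optimize_budget(pr, 0, mode = "atmost")
  expect_identical(v0$sequence, pr$sequence)
  expect_equal(v0$total_score, scan_sequence(pr$panel, pr$sequence,
                                             pr$percent)$E)
})

test_that("DP optima agree with brute force across random instances", {
  # the deeper 200-instance sweep lives in the acceptance suite; this spot
  # check keeps module-level feedback fast
  for (seed in 1:25) {
    pr <- random_design_problem(seed = seed, n = 9L + (seed %% 6L),
                                n_alleles = 1L + (seed %% 3L),
                                product_cap = 4000)
    bf <- brute_force_search(pr)
    best <- optimize_design(pr)
    expect_equal(best$total_score, bf$minimum)
    expect_equal(scan_sequence(pr$panel, best$sequence, pr$percent)$E,
                 best$total_score)
    # per-position feasibility
    res <- strsplit(best$sequence, "")[[1]]
    for (i in seq_along(res)) expect_true(res[i] %in% pr$allowed[[i]])
  }
})

test_that("near-optimal enumeration equals the filtered brute-force set", {
  for (seed in c(2L, 9L, 14L)) {
    pr <- random_design_problem(seed = seed, n = 12L, n_alleles = 2L,
                                product_cap = 3000)
    bf <- brute_force_search(pr)
    for (eps in 0:2) {
      enum <- enumerate_near_optimal(pr, epsilon = eps, limit = 100000)
      expect_equal(length(enum), sum(bf$scores <= bf$minimum + eps))
      scores <- vapply(enum, `[[`, 0, "total_score")
      expect_true(all(diff(scores) >= 0)) # ranked by score
      expect_true(all(scores <= bf$minimum + eps))
      seqs <- vapply(enum, `[[`, "", "sequence")
      expect_equal(anyDuplicated(seqs), 0L)
      # every reported score survives an independent rescan
      for (j in seq_along(enum)) {
        expect_equal(scan_sequence(pr$panel, seqs[j], pr$percent)$E,
                     scores[j])
      }
    }
  }
})

test_that("exact and at-most budgets are consistent with each other", {
  for (seed in c(4L, 12L)) {
    pr <- random_design_problem(seed = seed, n = 12L, product_cap = 2500)
    bf <- brute_force_search(pr)
    smax <- 4L
    atmost_prev <- Inf
    exact_best <- Inf
    for (s in 0:smax) {
      va <- optimize_budget(pr, s, mode = "atmost")
      sel <- bf$scores[bf$sub_counts <= s]
      expect_equal(va$total_score, min(sel))
      expect_lte(va$total_score, atmost_prev) # monotone in the budget
      atmost_prev <- va$total_score
      ve <- optimize_budget(pr, s, mode = "exact")
      sel_exact <- bf$scores[bf$sub_counts == s]
      if (length(sel_exact) == 0L) {
        expect_null(ve)
      } else {
        expect_equal(ve$total_score, min(sel_exact))
        exact_best <- min(exact_best, ve$total_score)
      }
    }
    # min over exactly-s optima equals the unconstrained optimum
    expect_equal(exact_best, optimize_design(pr)$total_score)
  }
})

test_that("ties break toward the wild type", {
  # a zero panel makes every sequence score 0; the optimizer must return
  # the wild type, not any of the equally scoring alternatives
  zero <- pocket_matrix("Z*0001", matrix(0, 9, 20),
                        thresholds = c("10" = 0.1))
  panel <- allele_panel(list(zero))
  seq <- random_aa_seq(11, 77)
  M <- random_allowed(seq, 78L, max_extra = 2L, product_cap = 2000)
  pr <- design_problem(seq, panel, 10, M)
  best <- optimize_design(pr)
  expect_identical(best$sequence, seq)
  # and the wild type ranks first among the enumerated co-optimal set
  enum <- enumerate_near_optimal(pr, epsilon = 0, limit = 100000)
  expect_identical(enum[[1L]]$sequence, seq)
  expect_equal(length(enum), prod(lengths(M$allowed)))
})

test_that("planted problems recover their closed-form optima", {
  for (seed in 1:8) {
    pp <- planted_problem(seed = seed, n = 12L + (seed %% 4L),
                          n_plants = 2L + (seed %% 2L),
                          n_alleles = 1L + (seed %% 2L))
    np <- length(pp$hot_positions)
    for (s in 0:np) {
      v <- optimize_budget(pp, s, mode = "atmost")
      expect_equal(v$total_score, pp$expected_optimum[s + 1L])
    }
    bf <- brute_force_search(pp)
    expect_equal(bf$minimum, pp$expected_optimum[np + 1L])
  }
})

test_that("one substitution at a promiscuous position clears overlapping windows", {
  # two planted hot positions one apart: every window containing either is
  # recognized; substituting both clears everything, and the overlap makes
  # single substitutions strictly less effective than their naive sum
  pp <- planted_problem(seed = 5L, n = 12L, hot_positions = c(6L, 7L),
                        n_alleles = 2L)
  expect_equal(optimize_budget(pp, 2L)$total_score, 0)
  v1 <- optimize_budget(pp, 1L)
  # all four windows contain both positions: one substitution fixes nothing
  # beyond windows unique to the substituted position (here none)
  expect_equal(v1$total_score, pp$expected_optimum[2L])
})

test_that("window cap forbids introducing new epitopes", {
  # construction where the unconstrained optimum must introduce an epitope:
  # a hot residue H at position 5 is seen once in each of windows 1..5 by
  # allele h1; replacing it with W silences h1 but creates a doubly
  # recognized window (c1, c2 fire on W at window position 1), so the free
  # optimum (2) beats the wild type (5) only by breaking the per-window cap
  n <- 13L
  hmat <- matrix(0, 9, 20); hmat[, match("H", AMINO_ACIDS)] <- 1
  cmat <- matrix(0, 9, 20); cmat[1, match("W", AMINO_ACIDS)] <- 1
  panel <- allele_panel(list(
    pocket_matrix("h1", hmat, thresholds = c("10" = 1)),
    pocket_matrix("c1", cmat, thresholds = c("10" = 1)),
    pocket_matrix("c2", cmat, thresholds = c("10" = 1))
  ))
  seq <- paste(c(rep("A", 4), "H", rep("A", 8)), collapse = "")
  allowed <- as.list(strsplit(seq, "")[[1]])
  allowed[[5]] <- c("H", "W")
  free <- design_problem(seq, panel, 10, allowed)
  capped <- design_problem(seq, panel, 10, allowed, window_cap = TRUE)
  expect_equal(scan_sequence(panel, seq, 10)$E, 5L)
  best_free <- optimize_design(free)
  expect_equal(best_free$total_score, 2)
  expect_equal(substr(best_free$sequence, 5, 5), "W")
  best_cap <- optimize_design(capped)
  expect_identical(best_cap$sequence, seq) # the cap forces the wild type
  expect_equal(best_cap$total_score, 5)
  expect_equal(brute_force_search(capped)$minimum, 5)

  # and on random instances the capped optimum never breaks any window
  for (seed in c(7L, 21L)) {
    pr_cap <- random_design_problem(seed = seed, n = 12L,
                                    product_cap = 2000, window_cap = TRUE)
    wt_counts <- scan_sequence(pr_cap$panel, pr_cap$sequence,
                               pr_cap$percent)$window_count
    best <- optimize_design(pr_cap)
    vp <- scan_sequence(pr_cap$panel, best$sequence, pr_cap$percent)
    expect_true(all(vp$window_count <= wt_counts))
    expect_equal(best$total_score, brute_force_search(pr_cap)$minimum)
  }
})

test_that("identical problems give bit-identical results", {
  a <- random_design_problem(seed = 6L, n = 12L)
  b <- random_design_problem(seed = 6L, n = 12L)
  expect_identical(optimize_design(a), optimize_design(b))
  ea <- enumerate_near_optimal(a, epsilon = 1, limit = 1000)
  eb <- enumerate_near_optimal(b, epsilon = 1, limit = 1000)
  expect_identical(ea, eb)
})

test_that("brute force histogram mass equals the variant count", {
  pr <- random_design_problem(seed = 10L, n = 11L, product_cap = 1500)
  M <- explicit_allowed(pr$sequence, pr$allowed)
  bf_all <- brute_force_search(pr)
  expect_equal(length(bf_all$scores), prod(lengths(M$allowed)))
  for (k in 0:2) {
    bfk <- brute_force_search(pr, k = k)
    expect_equal(length(bfk$scores), count_variants(M, k))
    expect_true(all(bfk$sub_counts == k))
  }
  expect_error(brute_force_search(pr, guard = 10), "guard")
})

test_that("degenerate inputs are rejected", {
  panel <- test_panel(1L, seed = 2L)
  expect_error(design_problem("AAAA", panel, 10,
                              explicit_allowed("AAAA", as.list(rep("A", 4)))),
               "at least 9")
  pr <- random_design_problem(seed = 3L, n = 10L)
  expect_error(optimize_budget(pr, -1), ">= 0")
  expect_error(enumerate_near_optimal(pr, epsilon = -1), ">= 0")
  expect_error(enumerate_near_optimal(pr, limit = 0), "limit")
})
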
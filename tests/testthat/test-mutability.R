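# Allowed-residue builders, penalty tables, tree weights and variant
# enumeration plumbing.

test_that("relative BLOSUM-62 rule reproduces its reference cases", {
  pep <- sakstar_peptide()
  M <- blosum_allowed(pep, max_diff = 4)
  sizes <- allowed_sizes(M)
  expect_length(sizes, 17L)
  expect_equal(round(mean(sizes), 1), 4.2)

  # proline tolerates no substitution within 4 of its diagonal score
  Mp <- blosum_allowed("PPPPPPPPP")
  expect_identical(Mp$allowed[[1L]], "P")

  # a huge tolerance admits the full alphabet
  Mall <- blosum_allowed(pep, max_diff = 30)
  expect_true(all(allowed_sizes(Mall) == 20L))

  # penalty flags: 0 on allowed residues (incl. wild type), 1 elsewhere
  expect_true(all(M$penalty[cbind(seq_len(17),
                                  match(M$residues, AMINO_ACIDS))] == 0))
  for (i in c(1L, 9L)) {
    expect_equal(sum(M$penalty[i, ] == 0), length(M$allowed[[i]]))
  }
})

test_that("tree-based weights follow bottom-up branch apportionment", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  w2 <- gsc_weights(two)
  expect_equal(unname(w2["A"]), unname(w2["B"]))

  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  ws <- gsc_weights(star)
  expect_true(all(abs(ws - ws[1L]) < 1e-12))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  w <- gsc_weights(tr)
  expect_equal(unname(w[c("A", "B", "C")]), c(1.5, 1.5, 2.0))

  zero <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_warning(wz <- gsc_weights(zero), "uniform")
  expect_true(all(wz == wz[1L]))
})

test_that("duplicating a leaf at zero distance splits only that weight", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  dup <- ape::read.tree(text = "(((A:0,A2:0):1,B:1):1,C:2);")
  w <- gsc_weights(tr)
  wd <- gsc_weights(dup)
  expect_equal(unname(wd["A"] + wd["A2"]), unname(w["A"]))
  expect_equal(unname(wd["B"]), unname(w["B"]))
  expect_equal(unname(wd["C"]), unname(w["C"]))
})

test_that("weighted conservation frequencies and penalties behave", {
  aln <- c(t = "KAV", s1 = "KAA", s2 = "KVV")
  wa <- weighted_alignment(aln, weights = c(t = 1.5, s1 = 1.5, s2 = 2.0),
                           target_id = "t")
  f <- weighted_frequencies(wa)
  expect_equal(unname(f[1, "K"]), 1)
  # column 2: A with weight 3.0, V with weight 2.0
  expect_equal(unname(f[2, "A"]), 0.6)
  expect_equal(unname(f[2, "V"]), 0.4)
  expect_equal(sum(f[2, ]), 1)

  M <- conservation_allowed(wa)
  expect_identical(M$allowed[[1L]], "K")
  expect_equal(unname(M$penalty[1, "K"]), 0)
  expect_equal(unname(M$penalty[2, "A"]), -log(0.6))

  # the documented penalty landmarks, in natural-log units
  expect_equal(round(-log(0.05), 2), 3.00)
  expect_equal(round(-log(0.01), 2), 4.61)
  penal <- conservation_allowed(wa, freq_min = 0.05)$penalty
  # largest penalty among residues actually present in the family: the
  # rarest observed frequency is 0.3 (A in the last column)
  observed <- penal[penal < -log(1e-6) - 1e-9]
  expect_equal(max(observed), -log(0.3), tolerance = 1e-12)
})

test_that("boundary frequencies are admitted inclusively", {
  # 20 equal-weight rows; exactly one carries V at column 2, so V's weighted
  # frequency sits exactly on the 5% default boundary
  aln <- stats::setNames(c("KA", rep("KA", 18), "KV"),
                         c("t", paste0("s", 1:19)))
  wa <- weighted_alignment(aln, weights = stats::setNames(rep(1, 20),
                                                          names(aln)),
                           target_id = "t")
  M <- conservation_allowed(wa, freq_min = 0.05)
  expect_true("V" %in% M$allowed[[2L]]) # f = 1/20 = 0.05 exactly
  expect_equal(unname(M$penalty[2L, "V"]), -log(0.05))
  Mtight <- conservation_allowed(wa, freq_min = 0.051)
  expect_false("V" %in% Mtight$allowed[[2L]]) # just beyond the boundary
  expect_true("A" %in% Mtight$allowed[[2L]])
})

test_that("all-gap columns fall back to the wild type with a warning", {
  aln <- c(t = "KA", s1 = "K-", s2 = "K-")
  wa <- weighted_alignment(aln, weights = c(t = 1, s1 = 1, s2 = 1),
                           target_id = "t")
  # drop the target's own contribution by weighting: simulate an all-gap
  # column via explicit column_map onto a gapped column
  aln2 <- c(s1 = "K-", s2 = "K-", t = "KA")
  wa2 <- suppressWarnings(weighted_alignment(aln2[1:2],
                                             weights = c(s1 = 1, s2 = 1),
                                             column_map = c(1L, 2L)))
  expect_warning(M <- conservation_allowed(wa2, target = "KA"), "all-gap")
  expect_identical(M$allowed[[2L]], "A")
})

test_that("ddG filtering is wild-type-referenced and boundary inclusive", {
  tab <- data.frame(
    position = rep(1:2, each = 3),
    wt_aa = rep(c("K", "L"), each = 3),
    mut_aa = c("K", "A", "D", "L", "M", "P"),
    ddg = c(0.5, 0.75, 0.7500001, -1.0, -0.75, 3.0),
    stringsAsFactors = FALSE
  )
  M <- foldx_allowed(tab, seq = "KL", margin = 0.25)
  # relative values: A = 0.25 (allowed, inclusive), D = 0.2500001 (excluded)
  expect_true("A" %in% M$allowed[[1L]])
  expect_false("D" %in% M$allowed[[1L]])
  expect_true(all(c("L", "M") %in% M$allowed[[2L]]))
  expect_false("P" %in% M$allowed[[2L]])
  expect_equal(unname(M$penalty[1L, "K"]), 0)
  expect_equal(unname(M$penalty[2L, "M"]), 0.25)

  dup <- rbind(tab, tab[2, ])
  expect_error(foldx_allowed(dup, seq = "KL"), "duplicate")
  expect_error(foldx_allowed(tab[tab$position == 1, ], seq = "KL"),
               "missing position")
})

test_that("variant counting matches explicit enumeration", {
  M <- explicit_allowed("ACD", list(c("A", "C"), c("C", "D", "E"), "D"))
  expect_equal(count_variants(M, 0), 1)
  expect_equal(enumerate_variants(M, 0), "ACD")
  v1 <- enumerate_variants(M, 1)
  expect_identical(v1, c("CCD", "ADD", "AED"))
  expect_equal(count_variants(M, 1), 3)
  expect_equal(count_variants(M, 2), 2)
  expect_identical(enumerate_variants(M, 2), c("CDD", "CED"))
  expect_equal(count_variants(M, 4), 0)

  for (seed in 1:5) {
    seq <- random_aa_seq(8, 200 + seed)
    M <- random_allowed(seq, seed, max_extra = 2L)
    for (k in 0:2) {
      vs <- enumerate_variants(M, k)
      expect_equal(length(vs), count_variants(M, k))
      expect_equal(anyDuplicated(vs), 0L)
      expect_true(all(vapply(vs, function(v) {
        sum(strsplit(v, "")[[1]] != strsplit(seq, "")[[1]]) == k
      }, TRUE)))
    }
  }
})

test_that("tightening thresholds never enlarges allowed sets", {
  pep <- sakstar_peptide()
  loose <- blosum_allowed(pep, max_diff = 6)
  tight <- blosum_allowed(pep, max_diff = 2)
  for (i in seq_len(nchar(pep))) {
    expect_true(all(tight$allowed[[i]] %in% loose$allowed[[i]]))
  }

  aln <- c(t = "KAV", s1 = "KAA", s2 = "KVV")
  wa <- weighted_alignment(aln, weights = c(t = 1, s1 = 1, s2 = 1),
                           target_id = "t")
  lo <- conservation_allowed(wa, freq_min = 0.05)
  hi <- conservation_allowed(wa, freq_min = 0.5)
  for (i in 1:3) expect_true(all(hi$allowed[[i]] %in% lo$allowed[[i]]))
})

test_that("intersection keeps the wild type and shrinks sets", {
  pep <- sakstar_peptide()
  a <- blosum_allowed(pep, max_diff = 4)
  b <- blosum_allowed(pep, max_diff = 2)
  both <- intersect_allowed(a, b)
  for (i in seq_len(nchar(pep))) {
    expect_true(both$residues[i] %in% both$allowed[[i]])
    expect_true(all(both$allowed[[i]] %in% a$allowed[[i]]))
  }
})
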
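# Shared fixtures and independent mini-oracles for the suite. The oracles
# here are written naively and separately from the package code paths they
# check (per-position lookup loops, explicit enumeration).

sakstar_peptide <- function() {
  read_target_fasta(system.file("extdata", "sakstar_71-87.fasta",
                                package = "deimmune"))
}

# reduced engine parameters for total-enumeration oracle tests
tiny_alphabet <- c("A", "C", "D", "E")
tiny_window <- 3L

# independent naive scorer: explicit per-position lookup-and-sum
naive_score <- function(matrix, pep) {
  res <- strsplit(pep, "")[[1]]
  tot <- 0
  for (p in seq_along(res)) {
    tot <- tot + matrix_weights(matrix)[p, res[p]]
  }
  tot
}

# independent naive scanner: double loop over windows x alleles
naive_scan_E <- function(panel, seq, percent) {
  n <- nchar(seq)
  w <- panel$window
  E <- 0L
  for (i in seq_len(n - w + 1L)) {
    pep <- substr(seq, i, i + w - 1L)
    for (m in panel$matrices) {
      if (score_peptide(m, pep) >= m$thresholds[[as.character(percent)]]) {
        E <- E + 1L
      }
    }
  }
  E
}

# enumerate every possible window peptide over an alphabet (oracle for the
# convolution calibration; alphabet^window must be tiny)
all_window_scores <- function(matrix) {
  alph <- matrix$alphabet
  w <- matrix$window
  grid <- expand.grid(rep(list(alph), w), stringsAsFactors = FALSE)
  apply(grid, 1L, function(r) {
    sum(vapply(seq_len(w),
               function(p) matrix_weights(matrix)[p, r[p]], 0))
  })
}

# small calibrated panel reused across tests
test_panel <- function(n_alleles = 2L, seed = 42L, percents = c(10L, 5L)) {
  random_panel(n_alleles, seed = seed, percents = percents)
}

random_aa_seq <- function(n, seed) {
  with_local_seed(seed, paste(sample(AMINO_ACIDS, n, TRUE), collapse = ""))
}
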
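#' Random pocket-profile panel
#'
#' Deterministic generator of synthetic scoring matrices: weights are drawn
#' from a normal distribution and rounded to the one-decimal grid, and
#' thresholds are calibrated exactly by convolution. A pure function of its
#' arguments (seed included); no attempt is made to imitate real HLA binding
#' motif statistics.
#'
#' @param n_alleles Number of matrices.
#' @param seed Integer seed.
#' @param weight_sd Standard deviation of the weight distribution before
#'   rounding (0 gives the all-zero degenerate matrix).
#' @param percents Percent levels to calibrate.
#' @param alphabet,window Engine parameters; the public surface pins the
#'   20-letter alphabet and window 9, and tests may relax both.
#' @return A calibrated [allele_panel()].
#' @export
random_panel <- function(n_alleles, seed, weight_sd = 0.5, percents = 1:10,
                         alphabet = AMINO_ACIDS, window = 9L) {
  stopifnot(n_alleles >= 1L)
  mats <- with_local_seed(seed, {
    lapply(seq_len(n_alleles), function(a) {
      wts <- round(matrix(stats::rnorm(window * length(alphabet),
                                       sd = weight_sd),
                          nrow = window), 1)
      pocket_matrix(sprintf("SYN*%04d", a), wts,
                    alphabet = alphabet, window = window)
    })
  })
  calibrate_panel(allele_panel(mats), percents = percents)
}

#' Random allowed-residue map
#'
#' Each position admits the wild type plus up to `max_extra` uniformly drawn
#' alternative residues (density `p_extra` per candidate). Optionally caps
#' the total product of set sizes so downstream exhaustive oracles stay
#' small.
#'
#' @param seq Target sequence.
#' @param seed Integer seed.
#' @param max_extra Maximum alternatives per position.
#' @param p_extra Probability a position gets any alternatives at all.
#' @param product_cap If finite, alternatives are dropped (deterministically,
#'   from the C-terminus backward) until the product of set sizes is at most
#'   this.
#' @param alphabet Residue alphabet.
#' @return An `"allowed_residues"` object (`source = "explicit"`).
#' @export
random_allowed <- function(seq, seed, max_extra = 2L, p_extra = 0.7,
                           product_cap = Inf, alphabet = AMINO_ACIDS) {
  res <- as_residues(seq, alphabet)
  n <- length(res)
  allowed <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      extras <- character(0)
      if (stats::runif(1) < p_extra && max_extra > 0L) {
        k <- sample.int(max_extra, 1L)
        extras <- sample(setdiff(alphabet, res[i]), k)
      }
      sort(union(res[i], extras))
    })
  })
  repeat {
    if (prod(lengths(allowed)) <= product_cap) break
    i <- max(which(lengths(allowed) > 1L))
    allowed[[i]] <- res[i]
  }
  sets <- lapply(seq_len(n), function(i) sort(union(allowed[[i]], res[i])))
  structure(
    list(sequence = paste(res, collapse = ""), residues = res,
         allowed = sets, source = "explicit", penalty = NULL,
         penalty_type = "none"),
    class = "allowed_residues"
  )
}

#' Random design problem for oracle testing
#'
#' A deterministic bundle of random sequence, random calibrated panel and
#' random allowed map, sized so that exhaustive brute-force scoring remains
#' cheap. Intended for property-style equivalence tests against
#' [brute_force_search()].
#'
#' @param seed Integer seed.
#' @param n Sequence length (>= window).
#' @param n_alleles Panel size.
#' @param percent Objective percent level.
#' @param max_extra Maximum alternative residues per position.
#' @param product_cap Cap on the product of allowed-set sizes.
#' @param window_cap Passed through to [design_problem()].
#' @param hit_fraction If not `NULL`, replace the calibrated thresholds by
#'   explicitly supplied ones at this tail fraction, so random instances
#'   carry a denser epitope signal than the 1..10% percentile grid yields
#'   (this also exercises the supplied-threshold override path).
#' @param alphabet,window Engine parameters.
#' @return A [design_problem()].
#' @export
random_design_problem <- function(seed, n = 12L, n_alleles = 2L,
                                  percent = 10L, max_extra = 2L,
                                  product_cap = 20000,
                                  window_cap = FALSE,
                                  hit_fraction = 0.3,
                                  alphabet = AMINO_ACIDS, window = 9L) {
  stopifnot(n >= window)
  seq <- with_local_seed(seed, {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  })
  panel <- random_panel(n_alleles, seed + 1L, percents = percent,
                        alphabet = alphabet, window = window)
  if (!is.null(hit_fraction)) {
    panel$matrices <- lapply(panel$matrices, function(m) {
      thr <- threshold_at_fraction(m, hit_fraction)
      lv <- unique(c(as.character(percent), "5"))
      set_thresholds(m, stats::setNames(rep(thr, length(lv)), lv))
    })
  }
  M <- random_allowed(seq, seed + 2L, max_extra = max_extra,
                      product_cap = product_cap, alphabet = alphabet)
  design_problem(seq, panel, percent = percent, allowed = M,
                 window_cap = window_cap)
}

#' Planted design problem with a closed-form optimum
#'
#' Constructs a problem whose optimal scores are known by construction: a
#' single "hot" residue carries weight 1.0 at every window position of every
#' allele, thresholds are fixed at 1.0, so a window is recognized by the
#' whole panel exactly when it contains at least one hot residue. Hot
#' residues are planted at chosen sequence positions; at each planted
#' position the allowed set is the wild type (hot) plus one cold residue, so
#' substituting it clears every window whose only hot content it was —
#' including the promiscuous case where one substitution clears several
#' overlapping recognized windows. The exact optimum for every substitution
#' budget is computed by direct subset bookkeeping over the planted
#' positions and stored with the problem.
#'
#' @param seed Integer seed (draws the background sequence and cold
#'   residues).
#' @param n Sequence length.
#' @param hot_positions Positions carrying the hot residue (default: drawn
#'   at random, possibly overlapping in coverage).
#' @param n_plants Number of planted positions when `hot_positions` is not
#'   given.
#' @param n_alleles Panel size.
#' @param alphabet,window Engine parameters.
#' @return A [design_problem()] with extra fields `hot_positions` and
#'   `expected_optimum` (numeric vector; entry `s + 1` is the optimal total
#'   score using at most `s` substitutions).
#' @export
planted_problem <- function(seed, n = 14L, hot_positions = NULL,
                            n_plants = 2L, n_alleles = 2L,
                            alphabet = AMINO_ACIDS, window = 9L) {
  stopifnot(n >= window)
  hot <- alphabet[length(alphabet)]
  cold_pool <- alphabet[-length(alphabet)]
  drawn <- with_local_seed(seed, {
    bg <- sample(cold_pool, n, replace = TRUE)
    hp <- hot_positions
    if (is.null(hp)) hp <- sort(sample.int(n, n_plants))
    cold <- sample(cold_pool, length(hp), replace = TRUE)
    list(bg = bg, hp = as.integer(hp), cold = cold)
  })
  res <- drawn$bg
  res[drawn$hp] <- hot
  seqstr <- paste(res, collapse = "")
  wts <- matrix(0, nrow = window, ncol = length(alphabet))
  wts[, length(alphabet)] <- 1
  mats <- lapply(seq_len(n_alleles), function(a) {
    pocket_matrix(sprintf("HOT*%04d", a), wts,
                  thresholds = c("10" = 1, "5" = 1),
                  alphabet = alphabet, window = window)
  })
  panel <- allele_panel(mats)
  allowed <- lapply(seq_len(n), function(i) {
    k <- match(i, drawn$hp)
    if (!is.na(k)) sort(c(hot, drawn$cold[k])) else res[i]
  })
  prob <- design_problem(seqstr, panel, percent = 10L, allowed = allowed)
  # closed-form optima: windows recognized are those containing at least one
  # unsubstituted hot position; try every subset of planted positions
  nw <- n - window + 1L
  covers <- lapply(drawn$hp, function(p) {
    seq(max(1L, p - window + 1L), min(nw, p))
  })
  np <- length(drawn$hp)
  best <- rep(Inf, np + 1L)
  for (mask in 0:(2^np - 1L)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(np) - 1L)) == 0L) # unsubstituted
    nsub <- np - length(keep)
    hit <- unique(unlist(covers[keep]))
    score <- n_alleles * length(hit)
    for (s in nsub:np) best[s + 1L] <- min(best[s + 1L], score)
  }
  prob$hot_positions <- drawn$hp
  prob$expected_optimum <- best
  prob
}
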
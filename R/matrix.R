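#' Pocket-profile scoring matrix for one MHC-II allele
#'
#' A pocket-profile matrix assigns an additive, position-specific binding
#' weight to each residue at each of the nine core positions of an HLA-DR
#' binding groove. A peptide's score is the sum of the nine weights; comparing
#' it to a per-allele percentile threshold classifies the peptide as a
#' predicted binder ("epitope") or not.
#'
#' Weights carry one decimal of precision (the precision of published
#' pocket-profile tables) and are stored internally as integers scaled by 10,
#' so that all score and threshold comparisons are exact integer arithmetic
#' with no floating-point tie ambiguity.
#'
#' @param allele Nonempty allele identifier, e.g. `"DRB1*0101"`.
#' @param weights Numeric matrix, `window` rows by `length(alphabet)` columns
#'   (rows = window positions, columns = residues in `alphabet` order).
#'   Values are read at one-decimal precision. A vector is accepted if it
#'   fills the matrix by row. Missing cells (`NA`) are treated as 0.
#' @param thresholds Optional named numeric vector mapping percent levels
#'   (names `"1"`..`"10"`) to score thresholds. Supplied thresholds override
#'   built-in calibration (see [calibrate_threshold()]).
#' @param alphabet Residue alphabet; the public surface uses the 20 standard
#'   amino acids. Reduced alphabets are supported for small-scale validation.
#' @param window Scoring window length; the public surface pins this at 9.
#'
#' @return An object of class `"pocket_matrix"`.
#' @seealso [score_peptide()], [calibrate_threshold()], [allele_panel()]
#' @export
pocket_matrix <- function(allele, weights, thresholds = NULL,
                          alphabet = AMINO_ACIDS, window = 9L) {
  if (!is.character(allele) || length(allele) != 1L || !nzchar(allele)) {
    stop("allele must be a nonempty string", call. = FALSE)
  }
  window <- as.integer(window)
  na <- length(alphabet)
  if (is.vector(weights) && !is.matrix(weights)) {
    weights <- matrix(weights, nrow = window, ncol = na, byrow = TRUE)
  }
  if (!is.matrix(weights) || nrow(weights) != window || ncol(weights) != na) {
    stop("weights must be a ", window, " x ", na, " matrix", call. = FALSE)
  }
  weights[is.na(weights)] <- 0
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  w10 <- round(weights * 10)
  if (max(abs(w10 - weights * 10)) > 1e-6) {
    warning("weights rounded to one-decimal precision", call. = FALSE)
  }
  storage.mode(w10) <- "integer"
  dimnames(w10) <- list(seq_len(window), alphabet)
  obj <- structure(
    list(
      allele = allele,
      w10 = w10,
      thresholds = NULL,
      alphabet = alphabet,
      window = window
    ),
    class = "pocket_matrix"
  )
  if (!is.null(thresholds)) obj <- set_thresholds(obj, thresholds)
  obj
}

#' @export
print.pocket_matrix <- function(x, ...) {
  cat("Pocket-profile matrix for allele", x$allele, "\n")
  cat("  window:", x$window, " alphabet:", length(x$alphabet), "residues\n")
  if (is.null(x$thresholds)) {
    cat("  thresholds: none set\n")
  } else {
    cat("  thresholds:",
        paste0(names(x$thresholds), "%=", x$thresholds, collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract the weight table of a pocket matrix in display units
#' @param matrix A [pocket_matrix()].
#' @return Numeric matrix (window x alphabet).
#' @export
matrix_weights <- function(matrix) {
  stopifnot(inherits(matrix, "pocket_matrix"))
  w <- matrix$w10 / 10
  w
}

# Attach/replace a percent -> threshold map; values kept in display units.
set_thresholds <- function(matrix, thresholds) {
  stopifnot(inherits(matrix, "pocket_matrix"))
  p <- as.integer(names(thresholds))
  if (anyNA(p) || any(p < 1L | p > 10L)) {
    stop("threshold names must be percent levels 1..10", call. = FALSE)
  }
  thr <- as.numeric(thresholds)
  names(thr) <- p
  thr <- thr[order(p)]
  ps <- sort(p)
  if (length(ps) > 1L && any(diff(thr[as.character(ps)]) > 1e-9)) {
    stop("thresholds must be non-increasing as the percent level loosens ",
         "(a 1% threshold must be >= the 10% threshold)", call. = FALSE)
  }
  matrix$thresholds <- thr
  matrix
}

# Integer-grid threshold for a percent level: a peptide is a hit iff its
# integer score (x10) is >= this value. Scores live on the x10 grid, so
# score >= theta  <=>  score10 >= ceiling(10 * theta).
theta10 <- function(matrix, percent) {
  percent <- as.integer(percent)
  if (is.na(percent) || percent < 1L || percent > 10L) {
    stop("percent must be an integer in 1..10", call. = FALSE)
  }
  thr <- matrix$thresholds[[as.character(percent)]]
  if (is.null(thr)) {
    stop("allele ", matrix$allele, " has no threshold at the ", percent,
         "% level; calibrate or supply one", call. = FALSE)
  }
  as.integer(ceiling(round(thr * 10, 6) - 1e-9))
}

#' Score a peptide with a pocket-profile matrix
#'
#' The score is the sum over window positions of the position-specific weight
#' of the residue found there. Deterministic, and independent of how the
#' weight table is stored.
#'
#' @param matrix A [pocket_matrix()].
#' @param pep Peptide string whose length equals the matrix window (9 for the
#'   standard surface). Non-standard residues are rejected with a message
#'   naming the offending character.
#' @return A single numeric score.
#' @examples
#' m <- pocket_matrix("DRB1*0101", matrix(0, 9, 20))
#' score_peptide(m, "AAAAAAAAA") # 0
#' @export
score_peptide <- function(matrix, pep) {
  stopifnot(inherits(matrix, "pocket_matrix"))
  res <- as_residues(pep, matrix$alphabet, what = "peptide")
  if (length(res) != matrix$window) {
    stop("peptide has length ", length(res), "; expected ", matrix$window,
         call. = FALSE)
  }
  idx <- residue_index(res, matrix$alphabet)
  sum(matrix$w10[cbind(seq_len(matrix$window), idx)]) / 10
}

# Exact distribution of integer (x10) scores over all |alphabet|^window
# peptides drawn uniformly: convolution of the per-position weight
# distributions. Returns list(support = integer scores, counts = double
# counts summing to |alphabet|^window). Counts stay below 2^53 for the
# 20^9 standard surface, so doubles are exact.
score_distribution10 <- function(matrix) {
  w10 <- matrix$w10
  window <- nrow(w10)
  lo <- sum(apply(w10, 1, min))
  hi <- sum(apply(w10, 1, max))
  len <- hi - lo + 1L
  dist <- numeric(len)
  # running convolution; offset of index 1 is the partial minimum sum
  dist[1L] <- 1
  off <- 0L
  cur_len <- 1L
  for (p in seq_len(window)) {
    tab <- table(w10[p, ])
    vals <- as.integer(names(tab))
    cnts <- as.numeric(tab)
    new_off <- off + min(vals)
    new_len <- cur_len + max(vals) - min(vals)
    nd <- numeric(new_len)
    for (k in seq_along(vals)) {
      sh <- off + vals[k] - new_off
      nd[(sh + 1L):(sh + cur_len)] <-
        nd[(sh + 1L):(sh + cur_len)] + dist[seq_len(cur_len)] * cnts[k]
    }
    dist <- nd
    off <- new_off
    cur_len <- new_len
  }
  list(support = off + seq_len(cur_len) - 1L, counts = dist)
}

#' Calibrate a percentile threshold by exact convolution
#'
#' Computes, exactly, the smallest score `theta` on the one-decimal grid such
#' that the fraction of all possible window peptides (uniform over the
#' alphabet, `20^9` for the standard surface) scoring at least `theta` is at
#' most `percent/100`. The full score distribution is obtained by convolving
#' the nine per-position weight distributions, so no sampling is involved.
#'
#' Explicitly supplied threshold tables (e.g. the published pocket-profile
#' distributions' own values) take precedence over this calibration when
#' present; calibration is the built-in fallback for synthetic or novel
#' matrices.
#'
#' @param matrix A [pocket_matrix()].
#' @param percent Integer percent level in 1..10.
#' @return The threshold as a numeric score (display units). As a side
#'   effect-free convenience, use [calibrate_panel()] to store thresholds.
#' @export
calibrate_threshold <- function(matrix, percent) {
  stopifnot(inherits(matrix, "pocket_matrix"))
  percent <- as.integer(percent)
  if (is.na(percent) || percent < 1L || percent > 10L) {
    stop("percent must be an integer in 1..10", call. = FALSE)
  }
  d <- score_distribution10(matrix)
  keep <- d$counts > 0
  support <- d$support[keep]
  counts <- d$counts[keep]
  if (length(support) == 1L) {
    warning("degenerate score distribution (all peptides score ",
            support / 10, "); no peptide will be recognized", call. = FALSE)
    return((support + 1L) / 10)
  }
  total <- sum(counts)
  tail_ge <- rev(cumsum(rev(counts))) / total
  # theta is the smallest attained score whose inclusive tail fits within
  # percent; the hit set {score >= theta} then holds at most percent% of all
  # peptides, and no smaller attained score would satisfy that.
  ok <- which(tail_ge <= percent / 100)
  if (length(ok) == 0L) {
    # even the maximum attained score is held by more than percent%
    return((support[length(support)] + 1L) / 10)
  }
  support[ok[1L]] / 10
}

# Threshold at an arbitrary tail fraction (not restricted to the 1..10%
# grid); used by synthetic generators that plant denser epitope signals.
threshold_at_fraction <- function(matrix, frac) {
  d <- score_distribution10(matrix)
  keep <- d$counts > 0
  support <- d$support[keep]
  counts <- d$counts[keep]
  if (length(support) == 1L) return((support + 1L) / 10)
  tail_ge <- rev(cumsum(rev(counts))) / sum(counts)
  ok <- which(tail_ge <= frac)
  if (length(ok) == 0L) return((support[length(support)] + 1L) / 10)
  support[ok[1L]] / 10
}

#' Calibrate and store thresholds for every allele of a panel
#'
#' @param panel An [allele_panel()].
#' @param percents Integer percent levels to calibrate (default 1..10).
#' @return The panel with each matrix's `thresholds` populated. Matrices with
#'   an explicitly supplied threshold at a level keep it untouched.
#' @export
calibrate_panel <- function(panel, percents = 1:10) {
  stopifnot(inherits(panel, "allele_panel"))
  panel$matrices <- lapply(panel$matrices, function(m) {
    thr <- m$thresholds
    for (p in percents) {
      key <- as.character(as.integer(p))
      if (is.null(thr) || is.na(thr[key]) || !(key %in% names(thr))) {
        v <- calibrate_threshold(m, p)
        if (is.null(thr)) thr <- stats::setNames(numeric(0), character(0))
        thr[key] <- v
      }
    }
    m$thresholds <- thr[order(as.integer(names(thr)))]
    m
  })
  panel
}

#' Bundle pocket matrices into an allele panel
#'
#' The panel is the unit the sequence scanner and the design optimizer
#' consume; the epitope score of a window is the number (equivalently the
#' fraction) of panel alleles whose threshold its pocket-profile score meets.
#'
#' @param matrices List of [pocket_matrix()] objects with distinct allele
#'   identifiers, identical windows and identical alphabets.
#' @return An object of class `"allele_panel"`.
#' @export
allele_panel <- function(matrices) {
  if (inherits(matrices, "pocket_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "pocket_matrix")))
  ids <- vapply(matrices, `[[`, "", "allele")
  if (anyDuplicated(ids)) {
    stop("duplicate allele identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  windows <- vapply(matrices, `[[`, 0L, "window")
  if (length(unique(windows)) != 1L) stop("matrices mix window lengths", call. = FALSE)
  alph <- matrices[[1L]]$alphabet
  for (m in matrices) {
    if (!identical(m$alphabet, alph)) stop("matrices mix alphabets", call. = FALSE)
  }
  structure(
    list(matrices = matrices, alleles = ids,
         window = windows[1L], alphabet = alph),
    class = "allele_panel"
  )
}

#' @export
print.allele_panel <- function(x, ...) {
  cat("Allele panel:", length(x$matrices), "pocket-profile matrices\n")
  cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  cat("  window:", x$window, " alphabet:", length(x$alphabet), "residues\n")
  invisible(x)
}

#' @export
length.allele_panel <- function(x) length(x$matrices)
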
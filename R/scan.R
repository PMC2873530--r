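#' Scan a protein sequence for predicted MHC-II epitopes
#'
#' Slides the panel's scoring window (9 residues on the standard surface)
#' along the sequence and, for every window start, records each allele's raw
#' pocket-profile score and whether it meets that allele's threshold at the
#' requested percent level (hit rule: score >= threshold, inclusive). The
#' total predicted epitope count E is the number of (window, allele) hits.
#'
#' @param panel An [allele_panel()] with thresholds set or calibrated at
#'   `percent`.
#' @param seq Protein sequence (string), length at least the window.
#' @param percent Integer percent level in 1..10; smaller is stricter.
#' @return An object of class `"epitope_profile"` with elements
#'   `window_start`, `scores` (windows x alleles), `hits` (logical),
#'   `window_count` (alleles hit per window), and `E` (total count).
#' @examples
#' m <- pocket_matrix("A1", matrix(c(rep(1, 20), rep(0, 160)), 9, 20,
#'                                 byrow = TRUE),
#'                    thresholds = c("10" = 1))
#' scan_sequence(allele_panel(list(m)), "AAAAAAAAAC", 10)
#' @export
scan_sequence <- function(panel, seq, percent = 10) {
  stopifnot(inherits(panel, "allele_panel"))
  res <- as_residues(seq, panel$alphabet)
  n <- length(res)
  w <- panel$window
  if (n < w) {
    stop("sequence has length ", n, "; at least ", w,
         " residues are required", call. = FALSE)
  }
  idx <- residue_index(res, panel$alphabet)
  nw <- n - w + 1L
  nal <- length(panel$matrices)
  scores10 <- matrix(0L, nrow = nw, ncol = nal)
  hits <- matrix(FALSE, nrow = nw, ncol = nal)
  # gather matrix: row = window, col = position-in-window
  gather <- outer(seq_len(nw) - 1L, seq_len(w), `+`)
  for (a in seq_len(nal)) {
    m <- panel$matrices[[a]]
    wvals <- matrix(m$w10[cbind(rep(seq_len(w), each = nw),
                                idx[as.vector(gather)])],
                    nrow = nw)
    s10 <- as.integer(rowSums(wvals))
    scores10[, a] <- s10
    hits[, a] <- s10 >= theta10(m, percent)
  }
  wc <- as.integer(rowSums(hits))
  colnames(scores10) <- colnames(hits) <- panel$alleles
  structure(
    list(
      sequence = paste(res, collapse = ""),
      n = n,
      window = w,
      percent = as.integer(percent),
      alleles = panel$alleles,
      window_start = seq_len(nw),
      scores = scores10 / 10,
      hits = hits,
      window_count = wc,
      E = sum(wc)
    ),
    class = "epitope_profile"
  )
}

#' @export
print.epitope_profile <- function(x, ...) {
  cat("Epitope profile (", x$percent, "% threshold): ", x$n, " residues, ",
      length(x$window_start), " windows, panel of ", length(x$alleles),
      " allele(s)\n", sep = "")
  cat("  total predicted epitopes E =", x$E, "\n")
  hot <- which(x$window_count > 0)
  if (length(hot)) {
    cat("  windows with hits:",
        paste0(hot, "(", x$window_count[hot], ")", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.epitope_profile <- function(x, ...) {
  data.frame(
    window_start = x$window_start,
    window_count = x$window_count,
    alleles_hit = vapply(seq_along(x$window_start), function(i) {
      paste(x$alleles[x$hits[i, ]], collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.epitope_profile <- function(x, variant = NULL, ...) {
  wt <- x$window_count
  if (is.null(variant)) {
    graphics::barplot(wt, names.arg = x$window_start,
                      xlab = "window start",
                      ylab = "alleles recognizing the 9-mer", ...)
  } else {
    stopifnot(inherits(variant, "epitope_profile"),
              length(variant$window_count) == length(wt))
    graphics::barplot(wt, names.arg = x$window_start, col = "grey30",
                      xlab = "window start",
                      ylab = "alleles recognizing the 9-mer", ...)
    graphics::barplot(variant$window_count, col = "orange", add = TRUE,
                      names.arg = rep("", length(wt)))
  }
  invisible(x)
}

#' Recognition statistics over random peptides
#'
#' Samples window-length peptides uniformly from the alphabet (i.e. from the
#' `20^9` possible 9-mers on the standard surface) and tabulates the fraction
#' recognized by exactly m panel alleles, m = 0..panel size. Reproducible for
#' a fixed seed; the caller's RNG state is untouched.
#'
#' @param panel An [allele_panel()] with thresholds available at `percent`.
#' @param percent Integer percent level in 1..10.
#' @param n_samples Number of peptides to sample (>= 1).
#' @param seed Integer RNG seed.
#' @return Numeric vector of length `panel size + 1` (names `"0"`..), summing
#'   to 1.
#' @export
recognition_histogram <- function(panel, percent = 10, n_samples = 1e5,
                                  seed = 1L) {
  stopifnot(inherits(panel, "allele_panel"), n_samples >= 1)
  n_samples <- as.integer(n_samples)
  w <- panel$window
  na <- length(panel$alphabet)
  nal <- length(panel$matrices)
  thetas <- vapply(panel$matrices, theta10, 0L, percent = percent)
  counts <- integer(nal + 1L)
  block <- 250000L
  with_local_seed(seed, {
    done <- 0L
    while (done < n_samples) {
      b <- min(block, n_samples - done)
      idx <- matrix(sample.int(na, b * w, replace = TRUE), nrow = b)
      nhit <- integer(b)
      for (a in seq_len(nal)) {
        s10 <- integer(b)
        w10 <- panel$matrices[[a]]$w10
        for (p in seq_len(w)) s10 <- s10 + w10[p, idx[, p]]
        nhit <- nhit + (s10 >= thetas[a])
      }
      tab <- tabulate(nhit + 1L, nbins = nal + 1L)
      counts <- counts + tab
      done <- done + b
    }
  })
  stats::setNames(counts / n_samples, 0:nal)
}

#' Exact tail probability of recognition for a single matrix
#'
#' The exact fraction of all possible window peptides scoring at least the
#' matrix's threshold at `percent`, from the convolution distribution (no
#' sampling).
#'
#' @param matrix A [pocket_matrix()] with a threshold at `percent`.
#' @param percent Integer percent level in 1..10.
#' @return Probability in `[0, 1]`.
#' @export
recognition_probability <- function(matrix, percent = 10) {
  stopifnot(inherits(matrix, "pocket_matrix"))
  th <- theta10(matrix, percent)
  d <- score_distribution10(matrix)
  sum(d$counts[d$support >= th]) / sum(d$counts)
}

#' Export wild-type vs variant epitope profiles as TSV
#'
#' Columns: `window_start`, `wt_count`, `variant_count`, `alleles_hit` (the
#' wild-type hit set). This is the tabular form behind per-window epitope
#' profile figures.
#'
#' @param wt_profile,variant_profile [scan_sequence()] results over the same
#'   sequence length and panel. `variant_profile` may be `NULL` to export the
#'   wild type alone.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_profile <- function(wt_profile, variant_profile = NULL, path) {
  stopifnot(inherits(wt_profile, "epitope_profile"))
  df <- as.data.frame(wt_profile)
  names(df)[names(df) == "window_count"] <- "wt_count"
  if (!is.null(variant_profile)) {
    check_profiles_compatible(wt_profile, variant_profile)
    df$variant_count <- variant_profile$window_count
  } else {
    df$variant_count <- NA_integer_
  }
  df <- df[, c("window_start", "wt_count", "variant_count", "alleles_hit")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a per-allele epitope map as TSV
#'
#' One row per (allele, wild-type epitope window): `allele`, `window_start`,
#' `window_end`, `eliminated` (1 if the variant no longer hits that allele in
#' that window). The tabular form behind per-allele epitope map figures.
#'
#' @inheritParams export_profile
#' @return `path`, invisibly.
#' @export
export_allele_map <- function(wt_profile, variant_profile = NULL, path) {
  stopifnot(inherits(wt_profile, "epitope_profile"))
  if (!is.null(variant_profile)) {
    check_profiles_compatible(wt_profile, variant_profile)
  }
  rows <- list()
  for (a in seq_along(wt_profile$alleles)) {
    ws <- which(wt_profile$hits[, a])
    if (length(ws) == 0L) next
    elim <- if (is.null(variant_profile)) {
      rep(NA_integer_, length(ws))
    } else {
      as.integer(!variant_profile$hits[ws, a])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      allele = wt_profile$alleles[a],
      window_start = ws,
      window_end = ws + wt_profile$window - 1L,
      eliminated = elim,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(allele = character(0), window_start = integer(0),
               window_end = integer(0), eliminated = integer(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_profiles_compatible <- function(a, b) {
  if (!inherits(b, "epitope_profile") ||
      a$n != b$n || !identical(a$alleles, b$alleles)) {
    stop("profiles differ in sequence length or allele panel", call. = FALSE)
  }
  invisible(TRUE)
}
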
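#' Read a pocket-profile matrix set (TSV dialect)
#'
#' The dialect stores one or more matrices per file. Each matrix block is:
#' \preformatted{
#' #allele DRB1*0101
#' 1<TAB>w(A)<TAB>...<TAB>w(Y)      # 20 one-decimal weights, alphabet order
#' ...                              # nine data lines, pos = 1..9
#' #threshold 10 2.2                # optional percent -> score lines
#' }
#' Published pocket-profile matrix sets (e.g. the ProPred/TEPITOPE HLA-DRB1
#' tables) converted to this dialect load directly; `#threshold` lines carry
#' their per-allele percentile cutoffs, which override built-in calibration.
#'
#' @param path File path.
#' @param alphabet Residue alphabet giving column order (default the 20
#'   standard amino acids).
#' @param window Expected number of data lines per matrix (default 9).
#' @return An [allele_panel()].
#' @export
read_matrix_set <- function(path, alphabet = AMINO_ACIDS, window = 9L) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  na <- length(alphabet)
  matrices <- list()
  cur_allele <- NULL
  cur_rows <- NULL
  cur_thr <- character(0)
  cur_thr_val <- numeric(0)
  flush <- function() {
    if (is.null(cur_allele)) return(invisible())
    got <- which(!is.na(cur_rows[, 1L]))
    if (length(got) != window) {
      stop(path, ": allele ", cur_allele, " has ", length(got),
           " data lines; expected ", window, call. = FALSE)
    }
    thr <- NULL
    if (length(cur_thr) > 0L) thr <- stats::setNames(cur_thr_val, cur_thr)
    matrices[[length(matrices) + 1L]] <<- pocket_matrix(
      cur_allele, cur_rows, thresholds = thr,
      alphabet = alphabet, window = window
    )
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#allele")) {
      flush()
      cur_allele <- trimws(sub("^#allele[ \t]+", "", line))
      if (!nzchar(cur_allele) || identical(cur_allele, line)) {
        stop(path, ":", ln, ": malformed #allele line", call. = FALSE)
      }
      cur_rows <- matrix(NA_real_, nrow = window, ncol = na)
      cur_thr <- character(0)
      cur_thr_val <- numeric(0)
    } else if (startsWith(line, "#threshold")) {
      if (is.null(cur_allele)) {
        stop(path, ":", ln, ": #threshold before any #allele", call. = FALSE)
      }
      parts <- strsplit(trimws(line), "[ \t]+")[[1L]]
      if (length(parts) != 3L) {
        stop(path, ":", ln, ": malformed #threshold line (need percent and value)",
             call. = FALSE)
      }
      pct <- suppressWarnings(as.integer(parts[2L]))
      val <- suppressWarnings(as.numeric(parts[3L]))
      if (is.na(pct) || pct < 1L || pct > 10L || is.na(val)) {
        stop(path, ":", ln, ": #threshold percent must be 1..10 and value numeric",
             call. = FALSE)
      }
      cur_thr <- c(cur_thr, as.character(pct))
      cur_thr_val <- c(cur_thr_val, val)
    } else if (startsWith(line, "#")) {
      next # comment
    } else {
      if (is.null(cur_allele)) {
        stop(path, ":", ln, ": data line before any #allele header", call. = FALSE)
      }
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(parts) != na + 1L) {
        stop(path, ":", ln, ": expected pos + ", na, " weight fields, got ",
             length(parts), call. = FALSE)
      }
      pos <- suppressWarnings(as.integer(parts[1L]))
      if (is.na(pos) || pos < 1L || pos > window) {
        stop(path, ":", ln, ": position field must be 1..", window, call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(parts[-1L]))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        stop(path, ":", ln, ": non-numeric weight in field ", bad + 1L,
             " (residue ", alphabet[bad], ")", call. = FALSE)
      }
      if (!is.na(cur_rows[pos, 1L])) {
        stop(path, ":", ln, ": duplicate data line for position ", pos,
             call. = FALSE)
      }
      cur_rows[pos, ] <- vals
    }
  }
  flush()
  if (length(matrices) == 0L) stop(path, ": no matrices found", call. = FALSE)
  allele_panel(matrices)
}

#' Write a panel in the matrix-set TSV dialect
#'
#' @param panel An [allele_panel()].
#' @param path Output file path.
#' @return `path`, invisibly. Output round-trips through [read_matrix_set()].
#' @export
write_matrix_set <- function(panel, path) {
  stopifnot(inherits(panel, "allele_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in panel$matrices) {
    writeLines(paste("#allele", m$allele), con)
    w <- m$w10 / 10
    for (p in seq_len(m$window)) {
      writeLines(paste(c(p, formatC(w[p, ], format = "f", digits = 1)),
                       collapse = "\t"), con)
    }
    if (!is.null(m$thresholds)) {
      for (k in names(m$thresholds)) {
        writeLines(paste("#threshold", k,
                         format(m$thresholds[[k]], trim = TRUE)), con)
      }
    }
  }
  invisible(path)
}
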
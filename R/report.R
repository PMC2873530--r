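#' Multi-metric evaluation of a designed variant
#'
#' Produces the standard report row for a variant: the epitope counts at the
#' 10% and 5% levels (both by rescanning the rendered sequence), and each
#' stability metric summed over the chosen substitutions only — B, the
#' number of substitutions the BLOSUM rule disallows; C, the summed
#' negative-log conservation penalties; and the summed relative ddG
#' (kcal/mol). The wild-type row therefore has B = 0, C = 0, ddG = 0. An
#' externally computed epitope count (e.g. from an independent predictor) can
#' be merged in as `S`; it is never computed here.
#'
#' @param variant A [design_variant()].
#' @param panel An [allele_panel()] with thresholds at the report levels.
#' @param percents Integer percent levels to report E at (default both 10
#'   and 5).
#' @param blosum,conservation,foldx Optional `"allowed_residues"` objects
#'   carrying the respective penalty tables (from [blosum_allowed()],
#'   [conservation_allowed()], [foldx_allowed()]). Every substituted position
#'   must be covered by each supplied table.
#' @param S Optional externally supplied integer score.
#' @return A one-row data frame of class `"variant_report"` with columns
#'   `variant`, `dot_string`, `mutations`, `E<percent>` per level, `B`, `C`,
#'   `ddG`, `S`.
#' @export
evaluate_variant <- function(variant, panel, percents = c(10L, 5L),
                             blosum = NULL, conservation = NULL,
                             foldx = NULL, S = NA_integer_) {
  stopifnot(inherits(variant, "design_variant"))
  subs <- variant$substitutions
  pick <- function(M, label) {
    if (is.null(M)) return(NA_real_)
    stopifnot(inherits(M, "allowed_residues"))
    if (is.null(M$penalty)) {
      stop("the ", label, " map carries no penalty table", call. = FALSE)
    }
    if (nrow(subs) == 0L) return(0)
    if (any(subs$position > nrow(M$penalty))) {
      stop("substitution outside ", label, " penalty-table coverage",
           call. = FALSE)
    }
    vals <- M$penalty[cbind(subs$position, match(subs$mut, AMINO_ACIDS))]
    if (anyNA(vals)) {
      stop("substitution outside ", label, " penalty-table coverage",
           call. = FALSE)
    }
    sum(vals)
  }
  Es <- vapply(percents, function(p) {
    scan_sequence(panel, variant$sequence, p)$E
  }, 0L)
  out <- data.frame(
    variant = mutation_names(variant),
    dot_string = dot_string(variant),
    mutations = variant$sub_count,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(percents)) out[[paste0("E", percents[j])]] <- Es[j]
  out$B <- pick(blosum, "BLOSUM")
  out$C <- pick(conservation, "conservation")
  out$ddG <- pick(foldx, "ddG")
  out$S <- S
  class(out) <- c("variant_report", class(out))
  out
}

#' @export
print.variant_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("C", "ddG")) {
    if (col %in% names(y)) y[[col]] <- ifelse(
      is.na(y[[col]]), "n/a", formatC(y[[col]], format = "f", digits = 2))
  }
  if ("S" %in% names(y)) y$S <- ifelse(is.na(y$S), "n/a", y$S)
  if ("variant" %in% names(y)) {
    y$variant[!nzchar(y$variant)] <- "wild type"
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Epitope-elimination statistics between two profiles
#'
#' Compares a wild-type and a variant epitope profile over the same sequence
#' length and panel: total epitopes deleted, percent reduction, epitopes
#' deleted per substitution, and the per-window / per-allele deltas.
#'
#' @param wt_profile,variant_profile [scan_sequence()] results.
#' @param n_substitutions Number of substitutions behind the variant
#'   (optional; enables the per-substitution rate).
#' @return List with `deleted`, `percent_reduction` (0 with `undefined =
#'   TRUE` when the wild type has no epitopes), `per_substitution`,
#'   `window_delta`, `allele_delta`.
#' @export
elimination_stats <- function(wt_profile, variant_profile,
                              n_substitutions = NA_integer_) {
  stopifnot(inherits(wt_profile, "epitope_profile"))
  check_profiles_compatible(wt_profile, variant_profile)
  deleted <- wt_profile$E - variant_profile$E
  undefined <- wt_profile$E == 0L
  pct <- if (undefined) 0 else 100 * deleted / wt_profile$E
  list(
    E_wt = wt_profile$E,
    E_variant = variant_profile$E,
    deleted = deleted,
    percent_reduction = pct,
    undefined = undefined,
    per_substitution = if (is.na(n_substitutions) || n_substitutions == 0L) {
      NA_real_
    } else deleted / n_substitutions,
    window_delta = wt_profile$window_count - variant_profile$window_count,
    allele_delta = colSums(wt_profile$hits) - colSums(variant_profile$hits)
  )
}

#' Write variant reports to TSV or JSON
#'
#' One row per variant with columns `variant`, `dot_string`, `mutations`,
#' the E columns, `B`, `C`, `ddG`, `S`. Real-valued columns are written with
#' two decimals in TSV; absent metrics render as `"n/a"`.
#'
#' @param reports A data frame of stacked [evaluate_variant()] rows.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_variant_reports <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(reports)
  if (format == "tsv") {
    out <- df
    for (col in c("C", "ddG")) {
      if (col %in% names(out)) {
        out[[col]] <- ifelse(is.na(df[[col]]), "n/a",
                             formatC(df[[col]], format = "f", digits = 2))
      }
    }
    if ("S" %in% names(out)) {
      out$S <- ifelse(is.na(df$S), "n/a", as.character(df$S))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a TSV variant report
#'
#' Round-trip reader for [write_variant_reports()] TSV output.
#'
#' @param path File path.
#' @return Data frame with `"n/a"` restored to `NA`.
#' @export
read_variant_reports <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "n/a",
                          colClasses = c(variant = "character",
                                         dot_string = "character"))
  df
}
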
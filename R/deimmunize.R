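#' Design deimmunized variants of a protein
#'
#' The top-level fitting function: scans the wild type, runs the suffix-state
#' dynamic program (optionally budgeted), enumerates the optimal and
#' near-optimal substitution sets, and evaluates every returned variant
#' against the panel and any supplied stability penalty tables.
#'
#' @param seq Target protein sequence (string), or a single-record FASTA path
#'   readable by [read_target_fasta()].
#' @param panel An [allele_panel()] with thresholds available at `percent`
#'   (and at the report levels).
#' @param allowed An `"allowed_residues"` object for the target (from
#'   [blosum_allowed()], [conservation_allowed()], [foldx_allowed()],
#'   [intersect_allowed()] or [explicit_allowed()]).
#' @param percent Objective percent level (1..10, default 10).
#' @param budget Optional substitution budget.
#' @param budget_mode `"atmost"` (default) or `"exact"`.
#' @param epsilon Near-optimality slack in window-allele-count units.
#' @param limit Maximum number of variants returned.
#' @param window_cap Forbid any window from scoring above its wild-type
#'   count (off by default).
#' @param offset Display numbering of the first residue (e.g. 71 for a
#'   peptide excised from a larger protein).
#' @param report_percents Percent levels for the report's E columns.
#' @param blosum,conservation,foldx Optional penalty-bearing
#'   `"allowed_residues"` objects for the report's B / C / ddG columns; the
#'   map supplied as `allowed` is reused automatically for its own column.
#' @return An object of class `"deimmunization"`: the problem, the wild-type
#'   profile, the ranked variants, and a stacked report data frame.
#' @examples
#' panel <- random_panel(2, seed = 7)
#' M <- blosum_allowed("TAYKEFRVVELDPSAKI")
#' fit <- deimmunize("TAYKEFRVVELDPSAKI", panel, M, budget = 2, offset = 71)
#' print(fit)
#' @export
deimmunize <- function(seq, panel, allowed, percent = 10L,
                       budget = NULL, budget_mode = c("atmost", "exact"),
                       epsilon = 0L, limit = 50L, window_cap = FALSE,
                       offset = 1L, report_percents = c(10L, 5L),
                       blosum = NULL, conservation = NULL, foldx = NULL) {
  budget_mode <- match.arg(budget_mode)
  if (length(seq) == 1L && file.exists(seq) && !grepl("^[A-Z]+$", seq)) {
    seq <- read_target_fasta(seq)
  }
  problem <- design_problem(seq, panel, percent = percent, allowed = allowed,
                            window_cap = window_cap)
  if (inherits(allowed, "allowed_residues")) {
    if (identical(allowed$penalty_type, "blosum_flag") && is.null(blosum)) {
      blosum <- allowed
    }
    if (identical(allowed$penalty_type, "conservation") &&
        is.null(conservation)) {
      conservation <- allowed
    }
    if (identical(allowed$penalty_type, "ddg") && is.null(foldx)) {
      foldx <- allowed
    }
  }
  wt_profile <- scan_sequence(panel, problem$sequence, percent)
  variants <- enumerate_near_optimal(problem, epsilon = epsilon,
                                     limit = limit, budget = budget,
                                     budget_mode = budget_mode,
                                     offset = offset)
  report_one <- function(v) {
    evaluate_variant(v, panel, percents = report_percents,
                     blosum = blosum, conservation = conservation,
                     foldx = foldx)
  }
  wt_variant <- design_variant(problem$sequence, problem$sequence,
                               offset = offset,
                               total_score = wt_profile$E)
  reports <- do.call(rbind, c(list(report_one(wt_variant)),
                              lapply(variants, report_one)))
  reports$total_score <- c(wt_profile$E,
                           vapply(variants, `[[`, 0, "total_score"))
  reports$role <- c("wild type", rep("variant", length(variants)))
  structure(
    list(
      problem = problem,
      percent = as.integer(percent),
      budget = budget, budget_mode = budget_mode,
      epsilon = as.integer(epsilon), limit = as.integer(limit),
      offset = as.integer(offset),
      wt_profile = wt_profile,
      optimum = if (length(variants)) variants[[1L]]$total_score else NA_real_,
      variants = variants,
      reports = reports,
      call = match.call()
    ),
    class = "deimmunization"
  )
}

#' @export
print.deimmunization <- function(x, ...) {
  cat("Deimmunization design (", x$percent, "% threshold, panel of ",
      length(x$problem$panel$matrices), " allele(s))\n", sep = "")
  cat("  wild-type epitope count E =", x$wt_profile$E, "\n")
  if (!is.null(x$budget)) {
    cat("  substitution budget:", x$budget, paste0("(", x$budget_mode, ")"),
        "\n")
  }
  if (length(x$variants) == 0L) {
    cat("  no feasible variant in the requested slice\n")
    return(invisible(x))
  }
  cat("  optimum total score =", x$optimum,
      "over", length(x$variants), "returned variant(s)\n\n")
  top <- utils::head(x$reports, 11L)
  print(structure(top, class = c("variant_report", class(top))))
  invisible(x)
}

#' @export
summary.deimmunization <- function(object, ...) {
  structure(
    list(
      wt_E = object$wt_profile$E,
      optimum = object$optimum,
      n_variants = length(object$variants),
      reports = object$reports,
      elimination = if (length(object$variants)) {
        best <- scan_sequence(object$problem$panel,
                              object$variants[[1L]]$sequence,
                              object$percent)
        elimination_stats(object$wt_profile, best,
                          object$variants[[1L]]$sub_count)
      } else NULL
    ),
    class = "summary.deimmunization"
  )
}

#' @export
print.summary.deimmunization <- function(x, ...) {
  cat("Wild-type E:", x$wt_E, "  optimum:", x$optimum,
      "  variants returned:", x$n_variants, "\n")
  if (!is.null(x$elimination)) {
    cat(sprintf("Best variant deletes %d epitopes (%.0f%% reduction",
                x$elimination$deleted, x$elimination$percent_reduction))
    if (!is.na(x$elimination$per_substitution)) {
      cat(sprintf(", %.1f per substitution", x$elimination$per_substitution))
    }
    cat(")\n\n")
  }
  print(structure(x$reports, class = c("variant_report",
                                       class(x$reports))))
  invisible(x)
}

#' @export
plot.deimmunization <- function(x, rank = 1L, ...) {
  if (length(x$variants) < rank) {
    plot(x$wt_profile, ...)
    return(invisible(x))
  }
  vp <- scan_sequence(x$problem$panel, x$variants[[rank]]$sequence,
                      x$percent)
  plot(x$wt_profile, variant = vp, ...)
  invisible(x)
}
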
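#' Read a single-record target FASTA
#'
#' Multi-record input is an error, not a silent first-record pick.
#'
#' @param path FASTA file path.
#' @return The sequence as a string.
#' @export
read_target_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L) {
    stop(path, ": expected exactly one sequence record, found ", length(set),
         call. = FALSE)
  }
  as.character(set[[1L]])
}

#' Read an aligned FASTA family alignment
#'
#' @param path Aligned FASTA path (rows may contain `-`/`.` gaps).
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(set), names(set))
  if (length(unique(nchar(out))) != 1L) {
    stop(path, ": alignment rows have unequal lengths", call. = FALSE)
  }
  out
}

#' Read a Newick tree with branch lengths
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(path, ": could not parse Newick tree", call. = FALSE)
  tr
}

#' Read a ddG substitution table (TSV dialect)
#'
#' Tab-separated with header `position	wt_aa	mut_aa	ddG_kcal_per_mol`, one
#' row per (position, mutant), wild-type self rows required (these anchor the
#' relative re-referencing in [foldx_allowed()]).
#'
#' @param path File path.
#' @return Data frame with columns `position`, `wt_aa`, `mut_aa`, `ddg`.
#' @export
read_ddg_table <- function(path) {
  if (!file.exists(path)) stop("ddG file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("position", "wt_aa", "mut_aa", "ddG_kcal_per_mol")
  if (!all(need %in% names(df))) {
    stop(path, ": header must name columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$ddG_kcal_per_mol)) {
    stop(path, ": ddG_kcal_per_mol column is not numeric", call. = FALSE)
  }
  data.frame(position = as.integer(df$position), wt_aa = df$wt_aa,
             mut_aa = df$mut_aa, ddg = df$ddG_kcal_per_mol,
             stringsAsFactors = FALSE)
}

#' Load a declarative run configuration
#'
#' A single YAML file describing a design run; command-line flags may
#' override individual fields. Defaults mirror the package defaults:
#' `max_diff` 4, `freq_min` 0.05, `margin` 0.25 kcal/mol, `percent` 10.
#'
#' Recognized fields: `sequence` (FASTA path), `offset`, `matrices` (matrix
#' set path), `percent`, `mutability` (one of `blosum`, `conservation`,
#' `foldx`, `intersection`, with method-specific sub-fields `max_diff`,
#' `msa`, `tree`, `freq_min`, `ddg_table`, `margin`, `sources`), `budget`,
#' `budget_mode`, `epsilon`, `limit`, `window_cap`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @param overrides Named list of fields replacing the file's values.
#' @return A validated config list of class `"run_config"`.
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  defaults <- list(offset = 1L, percent = 10L, budget = NULL,
                   budget_mode = "atmost", epsilon = 0L, limit = 50L,
                   window_cap = FALSE, seed = 1L, out_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("sequence", "matrices", "mutability")) {
    if (is.null(cfg[[k]])) {
      stop(path, ": config field ", sQuote(k), " is required", call. = FALSE)
    }
  }
  cfg$percent <- as.integer(cfg$percent)
  if (is.na(cfg$percent) || cfg$percent < 1L || cfg$percent > 10L) {
    stop(path, ": percent must be 1..10", call. = FALSE)
  }
  if (!is.list(cfg$mutability) || is.null(cfg$mutability$method)) {
    stop(path, ": mutability must be a mapping with a `method` field",
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

build_mutability <- function(spec, seq, base_dir = ".") {
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  method <- spec$method
  if (method == "blosum") {
    blosum_allowed(seq, max_diff = spec$max_diff %||% 4)
  } else if (method == "conservation") {
    aln <- read_alignment_fasta(resolve(spec$msa))
    weights <- NULL
    if (!is.null(spec$tree)) {
      tree <- read_newick_tree(resolve(spec$tree))
      weights <- gsc_weights(tree)
      missing_ids <- setdiff(names(aln), names(weights))
      if (length(missing_ids) > 0L) {
        stop("tree is missing alignment id(s): ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
      }
      weights <- weights[names(aln)]
    } else {
      message("no tree supplied; conservation uses uniform sequence weights")
    }
    wa <- if (is.null(weights)) {
      suppressWarnings(weighted_alignment(aln, NULL,
                                          target_id = spec$target_id))
    } else {
      weighted_alignment(aln, weights, target_id = spec$target_id)
    }
    M <- conservation_allowed(wa, freq_min = spec$freq_min %||% 0.05)
    if (!identical(M$sequence, seq)) {
      stop("alignment target row does not match the target sequence",
           call. = FALSE)
    }
    M
  } else if (method == "foldx") {
    tab <- read_ddg_table(resolve(spec$ddg_table))
    foldx_allowed(tab, seq = seq, margin = spec$margin %||% 0.25)
  } else if (method == "intersection") {
    parts <- lapply(spec$sources, build_mutability, seq = seq,
                    base_dir = base_dir)
    do.call(intersect_allowed, parts)
  } else {
    stop("unknown mutability method: ", sQuote(method), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate all inputs of a run configuration
#'
#' @param config A `"run_config"` (or a YAML path).
#' @param base_dir Directory against which relative paths resolve.
#' @return List with `problem` ([design_problem()]), `panel`, `allowed`,
#'   `seq`, and the config.
#' @export
load_inputs <- function(config, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- load_run_config(config)
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  seq <- read_target_fasta(resolve(config$sequence))
  panel <- read_matrix_set(resolve(config$matrices))
  panel <- calibrate_panel(panel, percents = unique(c(config$percent, 10L, 5L)))
  allowed <- build_mutability(config$mutability, seq, base_dir = base_dir)
  problem <- design_problem(seq, panel, percent = config$percent,
                            allowed = allowed,
                            window_cap = isTRUE(config$window_cap))
  list(problem = problem, panel = panel, allowed = allowed, seq = seq,
       config = config)
}

#' Execute a configured design run and write its reports
#'
#' Writes, under the configured output directory: `variants.tsv` and
#' `variants.json` (ranked report rows), `profile_wt.tsv` and, for the best
#' variant, `profile_best.tsv` and `allele_map_best.tsv`, plus a
#' machine-readable `manifest.json` echoing the configuration, the package
#' version and the seed. Outputs are deterministic for a fixed config and
#' seed. An infeasible slice (no variant within the requested budget)
#' produces an explicit empty result set with `status = "infeasible"`.
#'
#' @param config A `"run_config"` or YAML path.
#' @param base_dir Directory for resolving relative input paths.
#' @return Invisibly, a list with `status` (`"ok"` or `"infeasible"`), the
#'   fit, and the output paths.
#' @export
run_design <- function(config, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- load_run_config(config)
  }
  inputs <- load_inputs(config, base_dir = base_dir)
  fit <- deimmunize(
    inputs$seq, inputs$panel, inputs$allowed,
    percent = config$percent,
    budget = config$budget,
    budget_mode = config$budget_mode %||% "atmost",
    epsilon = config$epsilon %||% 0L,
    limit = config$limit %||% 50L,
    window_cap = isTRUE(config$window_cap),
    offset = config$offset %||% 1L
  )
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    variants_tsv = file.path(out_dir, "variants.tsv"),
    variants_json = file.path(out_dir, "variants.json"),
    profile_wt = file.path(out_dir, "profile_wt.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_variant_reports(fit$reports, paths$variants_tsv, "tsv")
  write_variant_reports(fit$reports, paths$variants_json, "json")
  export_profile(fit$wt_profile, NULL, paths$profile_wt)
  status <- "ok"
  if (length(fit$variants) > 0L) {
    best <- scan_sequence(inputs$panel, fit$variants[[1L]]$sequence,
                          config$percent)
    paths$profile_best <- file.path(out_dir, "profile_best.tsv")
    paths$allele_map_best <- file.path(out_dir, "allele_map_best.tsv")
    export_profile(fit$wt_profile, best, paths$profile_best)
    export_allele_map(fit$wt_profile, best, paths$allele_map_best)
  } else {
    status <- "infeasible"
  }
  manifest <- list(
    package = "deimmune",
    version = as.character(utils::packageVersion("deimmune")),
    status = status,
    seed = config$seed %||% 1L,
    config = unclass(config),
    wt_E = fit$wt_profile$E,
    optimum = fit$optimum,
    n_variants = length(fit$variants)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(status = status, fit = fit, paths = paths))
}
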
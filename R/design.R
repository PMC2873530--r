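#' Assemble a deimmunization design problem
#'
#' Couples a target sequence, an epitope scorer (allele panel at a fixed
#' percent level), and a per-position allowed-residue map into the unit the
#' dynamic program consumes. Substitution costs default to 1 per substituted
#' position (0 for the wild type); supplying `sub_cost` generalizes the
#' budget index to an integer substitution score.
#'
#' @param seq Target sequence (string), length >= the panel window.
#' @param panel An [allele_panel()] with thresholds available at `percent`.
#' @param percent Integer percent level in 1..10 used by the objective.
#' @param allowed An `"allowed_residues"` object for `seq`, or a plain list
#'   of per-position character vectors over the panel's alphabet (wild type
#'   always admitted).
#' @param sub_cost Optional function `(position, residue) -> non-negative
#'   integer cost`, or an n x alphabet numeric matrix. Wild-type cost must
#'   be 0.
#' @param window_cap If `TRUE`, no window of a designed variant may be
#'   recognized by more alleles than the corresponding wild-type window
#'   (windows violating this are assigned infinite score). Off by default:
#'   never-introduce-new-epitopes is an observed property of optimal designs,
#'   not a constraint, unless requested.
#' @return An object of class `"design_problem"`.
#' @export
design_problem <- function(seq, panel, percent = 10, allowed,
                           sub_cost = NULL, window_cap = FALSE) {
  stopifnot(inherits(panel, "allele_panel"))
  res <- as_residues(seq, panel$alphabet)
  n <- length(res)
  w <- panel$window
  if (n < w) {
    stop("sequence has length ", n, "; at least ", w, " residues are required",
         call. = FALSE)
  }
  if (inherits(allowed, "allowed_residues")) {
    if (!identical(allowed$sequence, paste(res, collapse = ""))) {
      stop("allowed-residue map was built for a different sequence",
           call. = FALSE)
    }
    sets <- allowed$allowed
  } else if (is.list(allowed)) {
    if (length(allowed) != n) {
      stop("allowed list must have one entry per position", call. = FALSE)
    }
    sets <- lapply(seq_len(n), function(i) {
      a <- as_residues(allowed[[i]], panel$alphabet,
                       what = paste0("allowed[", i, "]"))
      sort(union(a, res[i]))
    })
  } else {
    stop("allowed must be an allowed_residues object or a list", call. = FALSE)
  }
  # local residue order: wild type first, then the rest alphabetically, so
  # local index 1 is always the wild type and lexicographic comparison of
  # local indices realizes the wild-type-first tie-break.
  loc <- lapply(seq_len(n), function(i) {
    s <- sets[[i]]
    c(res[i], sort(setdiff(s, res[i])))
  })
  loc_idx <- lapply(loc, residue_index, alphabet = panel$alphabet)
  m <- lengths(loc)
  cost <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(sub_cost)) {
      ci <- c(0L, rep(1L, m[i] - 1L))
    } else if (is.function(sub_cost)) {
      ci <- vapply(loc[[i]], function(a) as.integer(sub_cost(i, a)), 0L)
    } else if (is.matrix(sub_cost)) {
      ci <- as.integer(sub_cost[i, loc[[i]]])
    } else {
      stop("sub_cost must be a function or a matrix", call. = FALSE)
    }
    if (anyNA(ci) || any(ci < 0L)) {
      stop("substitution costs must be non-negative integers", call. = FALSE)
    }
    if (ci[1L] != 0L) {
      stop("wild-type substitution cost must be 0 at position ", i,
           call. = FALSE)
    }
    cost[[i]] <- ci
  }
  thetas <- vapply(panel$matrices, theta10, 0L, percent = percent)
  wt_counts <- NULL
  if (window_cap) {
    wt_counts <- scan_sequence(panel, paste(res, collapse = ""),
                               percent)$window_count
  }
  structure(
    list(
      sequence = paste(res, collapse = ""),
      residues = res, n = n, window = w,
      panel = panel, percent = as.integer(percent), thetas = thetas,
      allowed = sets, loc = loc, loc_idx = loc_idx, m = m, cost = cost,
      window_cap = window_cap, wt_window_counts = wt_counts
    ),
    class = "design_problem"
  )
}

#' @export
print.design_problem <- function(x, ...) {
  cat("Design problem: n =", x$n, "residues,", length(x$panel$matrices),
      "allele(s) at the ", paste0(x$percent, "%"), "level\n")
  cat("  allowed residues/position: mean", round(mean(x$m), 1),
      "(range", min(x$m), "-", max(x$m), ")\n")
  cat("  state space:", format(sum(vapply(
    seq(x$window, x$n),
    function(i) prod(x$m[(i - x$window + 2L):i]), 0
  )), big.mark = ","), "suffix states\n")
  if (x$window_cap) cat("  per-window no-new-epitope cap: on\n")
  invisible(x)
}

# Epitope count (alleles hit) for every residue combination of the window
# ending at position i, as a flat array with dims m[(i-w+1)..i], first
# position fastest. Infinite where the window cap is violated.
window_count_array <- function(problem, i) {
  w <- problem$window
  ps <- (i - w + 1L):i
  cnt <- 0
  for (a in seq_along(problem$panel$matrices)) {
    w10 <- problem$panel$matrices[[a]]$w10
    s <- w10[1L, problem$loc_idx[[ps[1L]]]]
    for (p in 2L:w) {
      s <- as.vector(outer(s, w10[p, problem$loc_idx[[ps[p]]]], `+`))
    }
    cnt <- cnt + (s >= problem$thetas[a])
  }
  cnt <- as.numeric(cnt)
  if (problem$window_cap) {
    start <- i - w + 1L
    cnt[cnt > problem$wt_window_counts[start]] <- Inf
  }
  cnt
}

# All per-window count arrays, indexed by window end position.
window_count_arrays <- function(problem) {
  out <- vector("list", problem$n)
  for (i in seq(problem$window, problem$n)) {
    out[[i]] <- window_count_array(problem, i)
  }
  out
}

# column-min over the first dimension of a flat array
min_over_first_dim <- function(x, d1) {
  M <- matrix(x, nrow = d1)
  out <- M[1L, ]
  if (d1 > 1L) for (r in 2L:d1) out <- pmin(out, M[r, ])
  out
}

# Forward tables T[i, X]: best total epitope count for the prefix ending at
# i whose last (w-1) residues form suffix state X. Base column i = w-1 is 0
# for every state; only combinations of allowed residues ever exist.
build_T <- function(problem, C = window_count_arrays(problem)) {
  w <- problem$window
  n <- problem$n
  m <- problem$m
  tables <- vector("list", n)
  tables[[w - 1L]] <- numeric(prod(m[seq_len(w - 1L)]))
  for (i in seq(w, n)) {
    S <- C[[i]] + tables[[i - 1L]]      # recycles over the last dimension
    tables[[i]] <- min_over_first_dim(S, m[i - w + 1L])
  }
  list(tables = tables, C = C)
}

# Budget tables R[i, X, s]: as build_T but with an exact substitution-cost
# index s = 0..s_max. Stored as matrices (states x s+1); unreachable
# (state, s) combinations hold Inf.
build_R <- function(problem, s_max, C = window_count_arrays(problem)) {
  w <- problem$window
  n <- problem$n
  m <- problem$m
  s_max <- as.integer(s_max)
  if (s_max < 0L) stop("substitution budget must be >= 0", call. = FALSE)
  tables <- vector("list", n)
  # base: cost of the first (w-1)-mer
  base_cost <- problem$cost[[1L]]
  for (p in seq(2L, w - 1L)) {
    base_cost <- as.vector(outer(base_cost, problem$cost[[p]], `+`))
  }
  R0 <- matrix(Inf, nrow = length(base_cost), ncol = s_max + 1L)
  ok <- base_cost <= s_max
  R0[cbind(which(ok), base_cost[ok] + 1L)] <- 0
  tables[[w - 1L]] <- R0
  for (i in seq(w, n)) {
    d1 <- m[i - w + 1L]
    B <- nrow(tables[[i - 1L]])        # prod over positions (i-w+1)..(i-1)
    B2 <- B / d1                        # prod over positions (i-w+2)..(i-1)
    mi <- m[i]
    Rnew <- matrix(Inf, nrow = B2 * mi, ncol = s_max + 1L)
    ci <- problem$cost[[i]]
    Cmat <- matrix(C[[i]], nrow = B)    # column v = slice x_i = v
    for (s in 0:s_max) {
      for (v in seq_len(mi)) {
        sp <- s - ci[v]
        if (sp < 0L) next
        Q <- Cmat[, v] + tables[[i - 1L]][, sp + 1L]
        Rnew[(v - 1L) * B2 + seq_len(B2), s + 1L] <-
          min_over_first_dim(Q, d1)
      }
    }
    tables[[i]] <- Rnew
  }
  list(tables = tables, C = C, s_max = s_max)
}

# strides for linear indexing of a flat array with dims m[ps]
dim_strides <- function(m, ps) {
  cumprod(c(1L, m[ps[-length(ps)]]))
}

decode_state <- function(lin, m, ps) {
  out <- integer(length(ps))
  lin <- lin - 1L
  for (k in seq_along(ps)) {
    out[k] <- lin %% m[ps[k]] + 1L
    lin <- lin %/% m[ps[k]]
  }
  out
}

# Depth-first near-optimal traceback (suffix-state walk with slack), shared
# by the plain and the budget engines. Yields local-index vectors (length n)
# of every feasible sequence whose total score is <= bound. `targets` is
# NULL for the plain engine or the set of admissible end costs s for the
# budget engine.
enumerate_traces <- function(problem, dp, bound, targets = NULL,
                             max_solutions = 2e5) {
  w <- problem$window
  n <- problem$n
  m <- problem$m
  C <- dp$C
  tables <- dp$tables
  budgeted <- !is.null(targets)
  results <- vector("list", 256L)
  nres <- 0L
  fixed <- integer(n)
  emit <- function(state) {
    fixed[seq_len(w - 1L)] <<- state
    nres <<- nres + 1L
    if (nres > max_solutions) {
      stop("more than ", max_solutions, " solutions within the slack; ",
           "reduce epsilon or raise max_solutions", call. = FALSE)
    }
    if (nres > length(results)) length(results) <<- 2L * nres
    results[[nres]] <<- fixed
  }
  table_val <- function(i, lin, s) {
    if (budgeted) {
      if (s < 0L) return(Inf)
      tables[[i]][lin, s + 1L]
    } else {
      tables[[i]][lin]
    }
  }
  walk <- function(i, state, lin, s, acc) {
    # state = local indices at positions (i-w+2)..i; lin = its linear index
    if (i == w - 1L) {
      emit(state)
      return(invisible())
    }
    fixed[i] <<- state[w - 1L]
    d1 <- m[i - w + 1L]
    # predecessor state (a, state[1..w-2]) and window (a, state);
    # tail_lin = 0-based index of state[1..w-2] over dims m[(i-w+2)..(i-1)]
    tail_lin <- (lin - 1L) %% prod(m[(i - w + 2L):(i - 1L)])
    sp <- s
    if (budgeted) sp <- s - problem$cost[[i]][state[w - 1L]]
    if (budgeted && sp < 0L) return(invisible())
    win_base <- (lin - 1L) * d1   # window dims (a, state): a fastest
    prev_base <- tail_lin * d1
    for (a in seq_len(d1)) {
      cwin <- C[[i]][win_base + a]
      if (!is.finite(cwin)) next
      tv <- table_val(i - 1L, prev_base + a, sp)
      if (tv + cwin + acc <= bound) {
        walk(i - 1L,
             c(a, state[-(w - 1L)]),
             prev_base + a,
             sp,
             acc + cwin)
      }
    }
    invisible()
  }
  # entry points at column n
  if (budgeted) {
    for (s_end in targets) {
      col <- tables[[n]][, s_end + 1L]
      for (lin in which(col <= bound)) {
        walk(n, decode_state(lin, m, (n - w + 2L):n), lin, s_end, 0)
      }
    }
  } else {
    for (lin in which(tables[[n]] <= bound)) {
      walk(n, decode_state(lin, m, (n - w + 2L):n), lin, NA_integer_, 0)
    }
  }
  if (nres == 0L) return(list())
  results[seq_len(nres)]
}

# order variants by (total score, substitution count, local-index
# lexicographic with the wild type first); returns ordering permutation
order_variants <- function(problem, locidx_list, scores) {
  subs <- vapply(locidx_list, function(v) sum(v != 1L), 0L)
  idxmat <- do.call(rbind, locidx_list)
  args <- c(list(scores, subs),
            lapply(seq_len(ncol(idxmat)), function(j) idxmat[, j]))
  do.call(order, args)
}

locidx_to_variant <- function(problem, locidx, total_score, offset = 1L) {
  res <- vapply(seq_len(problem$n),
                function(i) problem$loc[[i]][locidx[i]], "")
  design_variant(paste(res, collapse = ""), problem$sequence,
                 offset = offset, total_score = total_score)
}

# total score of a local-index assignment, straight off the window arrays
trace_score <- function(problem, C, locidx) {
  w <- problem$window
  tot <- 0
  for (i in seq(w, problem$n)) {
    ps <- (i - w + 1L):i
    strides <- dim_strides(problem$m, ps)
    lin <- sum((locidx[ps] - 1L) * strides) + 1L
    tot <- tot + C[[i]][lin]
  }
  tot
}

#' Globally optimal deimmunized variant
#'
#' Runs the suffix-state dynamic program: `T[i, X]` is the best achievable
#' total epitope count for the prefix ending at position `i` whose final
#' `window - 1` residues form the string `X`, every residue drawn from the
#' allowed map. The optimum is `min_X T[n, X]`; ties are broken in favor of
#' the wild type (fewer substitutions, then lexicographically with the
#' wild-type residue ordered first at each position), so the wild type itself
#' is returned when nothing beats it. Only suffix states composed of allowed
#' residues are ever materialized.
#'
#' @param problem A [design_problem()].
#' @param offset Display numbering offset for the returned variant.
#' @return A [design_variant()] with `total_score` set; the optimum never
#'   exceeds the wild-type scan score.
#' @export
optimize_design <- function(problem, offset = 1L) {
  stopifnot(inherits(problem, "design_problem"))
  dp <- build_T(problem)
  opt <- min(dp$tables[[problem$n]])
  traces <- enumerate_traces(problem, dp, opt)
  scores <- vapply(traces, trace_score, 0, problem = problem, C = dp$C)
  ord <- order_variants(problem, traces, scores)
  locidx_to_variant(problem, traces[[ord[1L]]], opt, offset)
}

#' Optimal variant under a substitution budget
#'
#' Extends the dynamic program with an exact substitution-cost index:
#' `R[i, X, s]` is the best total epitope count using exactly cost `s`,
#' accumulated from the N-terminal `window - 1`-mer onward (1 per substituted
#' position by default, or the problem's integer substitution score). With
#' `mode = "exact"` the optimum uses exactly cost `s`; with `mode = "atmost"`
#' it is the best over all costs up to `s` (non-increasing in `s`, and equal
#' to the unconstrained optimum once `s` is large enough).
#'
#' @param problem A [design_problem()].
#' @param s Substitution budget (cost bound, >= 0).
#' @param mode `"exact"` or `"atmost"`.
#' @param offset Display numbering offset for the returned variant.
#' @return A [design_variant()], or `NULL` if no variant attains exactly `s`
#'   (possible only in `"exact"` mode).
#' @export
optimize_budget <- function(problem, s, mode = c("atmost", "exact"),
                            offset = 1L) {
  stopifnot(inherits(problem, "design_problem"))
  mode <- match.arg(mode)
  s <- as.integer(s)
  if (s < 0L) stop("substitution budget must be >= 0", call. = FALSE)
  dp <- build_R(problem, s)
  targets <- if (mode == "exact") s else 0:s
  vals <- dp$tables[[problem$n]][, targets + 1L, drop = FALSE]
  opt <- min(vals)
  if (!is.finite(opt)) return(NULL)
  traces <- enumerate_traces(problem, dp, opt, targets = targets)
  scores <- vapply(traces, trace_score, 0, problem = problem, C = dp$C)
  ord <- order_variants(problem, traces, scores)
  locidx_to_variant(problem, traces[[ord[1L]]], opt, offset)
}

#' Enumerate optimal and near-optimal variants
#'
#' Modified dynamic-programming traceback: every feasible variant whose total
#' epitope count is within `epsilon` of the optimum is produced exactly once,
#' by walking suffix states backward while the accumulated score plus the
#' table value still fits under `optimum + epsilon`. Results are ranked by
#' (score, substitution count, lexicographic sequence with the wild-type
#' residue first at each position), so the wild type leads any score tie it
#' participates in. `epsilon = 0` yields the full co-optimal set.
#'
#' @param problem A [design_problem()].
#' @param epsilon Non-negative integer slack, in window-allele-count units
#'   (the natural integer grid of the objective).
#' @param limit Maximum number of variants to return (> 0).
#' @param budget Optional substitution budget; restricts enumeration to the
#'   exactly-`budget` slice (`budget_mode = "exact"`) or to at most `budget`
#'   (`"atmost"`), with the optimum taken within that slice.
#' @param budget_mode `"exact"` or `"atmost"`; ignored without a budget.
#' @param offset Display numbering offset.
#' @param max_solutions Internal guard on the enumeration size.
#' @return List of [design_variant()] objects in rank order (possibly empty
#'   when an exact budget is infeasible).
#' @export
enumerate_near_optimal <- function(problem, epsilon = 0, limit = 100L,
                                   budget = NULL,
                                   budget_mode = c("atmost", "exact"),
                                   offset = 1L, max_solutions = 2e5) {
  stopifnot(inherits(problem, "design_problem"))
  budget_mode <- match.arg(budget_mode)
  epsilon <- as.integer(epsilon)
  if (epsilon < 0L) stop("epsilon must be >= 0", call. = FALSE)
  limit <- as.integer(limit)
  if (is.na(limit) || limit <= 0L) stop("limit must be > 0", call. = FALSE)
  if (is.null(budget)) {
    dp <- build_T(problem)
    opt <- min(dp$tables[[problem$n]])
    targets <- NULL
  } else {
    budget <- as.integer(budget)
    if (budget < 0L) stop("substitution budget must be >= 0", call. = FALSE)
    dp <- build_R(problem, budget)
    targets <- if (budget_mode == "exact") budget else 0:budget
    opt <- min(dp$tables[[problem$n]][, targets + 1L])
    if (!is.finite(opt)) return(list())
  }
  bound <- opt + epsilon
  traces <- enumerate_traces(problem, dp, bound, targets = targets,
                             max_solutions = max_solutions)
  if (length(traces) == 0L) return(list())
  # distinct traces map to distinct sequences under suffix states, but keep
  # the sequence as the identity key anyway
  seqs <- vapply(traces, function(v) paste(v, collapse = ","), "")
  keep <- !duplicated(seqs)
  traces <- traces[keep]
  scores <- vapply(traces, trace_score, 0, problem = problem, C = dp$C)
  ord <- order_variants(problem, traces, scores)
  ord <- ord[seq_len(min(limit, length(ord)))]
  lapply(ord, function(j) {
    locidx_to_variant(problem, traces[[j]], scores[j], offset)
  })
}

#' Brute-force scoring oracle
#'
#' Exhaustively scores every sequence in the product of the allowed sets (or
#' only the exactly-`k`-substitution slice) by direct window-by-window
#' rescoring, independent of the dynamic program. Intended as a testing
#' oracle and for exhaustive landscape analyses of small designs.
#'
#' @param problem A [design_problem()].
#' @param k If given, restrict to sequences with exactly `k` substituted
#'   positions.
#' @param guard Refuse to enumerate more than this many sequences.
#' @param offset Display numbering offset for the reported minima.
#' @return List with `scores` (integer per enumerated sequence; `Inf` marks
#'   sequences violating the window cap), `sub_counts`, `sub_costs`,
#'   `histogram` (table of finite scores), `median`, `minimum`, and
#'   `argmin` (list of [design_variant()] at the minimum, in deterministic
#'   rank order).
#' @export
brute_force_search <- function(problem, k = NULL, guard = 1e6, offset = 1L) {
  stopifnot(inherits(problem, "design_problem"))
  n <- problem$n
  m <- problem$m
  if (is.null(k)) {
    total <- prod(m)
    if (total > guard) {
      stop("enumeration size ", format(total, big.mark = ","),
           " exceeds the guard", call. = FALSE)
    }
    total <- as.integer(total)
    locs <- matrix(1L, nrow = total, ncol = n)
    rep_each <- 1L
    for (i in seq_len(n)) {
      locs[, i] <- rep(rep(seq_len(m[i]), each = rep_each),
                       length.out = total)
      rep_each <- rep_each * m[i]
    }
  } else {
    k <- as.integer(k)
    total <- count_variants_local(problem, k)
    if (total > guard) {
      stop("enumeration size ", format(total, big.mark = ","),
           " exceeds the guard", call. = FALSE)
    }
    locs <- enumerate_k_local(problem, k)
    total <- nrow(locs)
  }
  if (total == 0L) {
    return(list(scores = numeric(0), sub_counts = integer(0),
                sub_costs = integer(0), histogram = table(numeric(0)),
                median = NA_real_, minimum = NA_real_, argmin = list()))
  }
  w <- problem$window
  nal <- length(problem$panel$matrices)
  # residue alphabet indices per (sequence, position)
  aidx <- matrix(0L, nrow = total, ncol = n)
  for (i in seq_len(n)) aidx[, i] <- problem$loc_idx[[i]][locs[, i]]
  scores <- numeric(total)
  for (ws in seq_len(n - w + 1L)) {
    wc <- integer(total)
    for (a in seq_len(nal)) {
      w10 <- problem$panel$matrices[[a]]$w10
      s10 <- integer(total)
      for (p in seq_len(w)) s10 <- s10 + w10[p, aidx[, ws + p - 1L]]
      wc <- wc + (s10 >= problem$thetas[a])
    }
    if (problem$window_cap) {
      bad <- wc > problem$wt_window_counts[ws]
      scores[bad] <- Inf
      scores[!bad] <- scores[!bad] + wc[!bad]
    } else {
      scores <- scores + wc
    }
  }
  sub_counts <- as.integer(rowSums(locs != 1L))
  costmat <- matrix(0L, nrow = total, ncol = n)
  for (i in seq_len(n)) costmat[, i] <- problem$cost[[i]][locs[, i]]
  sub_costs <- as.integer(rowSums(costmat))
  finite <- is.finite(scores)
  minimum <- if (any(finite)) min(scores[finite]) else NA_real_
  argmin <- list()
  if (!is.na(minimum)) {
    hit <- which(scores == minimum)
    traces <- lapply(hit, function(r) locs[r, ])
    ord <- order_variants(problem, traces, scores[hit])
    argmin <- lapply(ord, function(j) {
      locidx_to_variant(problem, traces[[j]], minimum, offset)
    })
  }
  list(
    scores = scores,
    sub_counts = sub_counts,
    sub_costs = sub_costs,
    histogram = table(scores[finite]),
    median = if (any(finite)) stats::median(scores[finite]) else NA_real_,
    minimum = minimum,
    argmin = argmin
  )
}

count_variants_local <- function(problem, k) {
  m <- problem$m - 1L
  coefs <- numeric(k + 1L)
  coefs[1L] <- 1
  for (i in seq_len(problem$n)) {
    upper <- min(k, i)
    if (upper >= 1L) {
      js <- upper:1L
      coefs[js + 1L] <- coefs[js + 1L] + coefs[js] * m[i]
    }
  }
  coefs[k + 1L]
}

# local-index rows for every exactly-k-substitution assignment, in the same
# deterministic order as enumerate_variants()
enumerate_k_local <- function(problem, k) {
  n <- problem$n
  if (k == 0L) return(matrix(1L, nrow = 1L, ncol = n))
  if (k > n) return(matrix(1L, nrow = 0L, ncol = n))
  rows <- list()
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (pos in subsets) {
    alts <- lapply(pos, function(i) seq(2L, length.out = problem$m[i] - 1L))
    if (any(lengths(alts) == 0L)) next
    grid <- expand.grid(rev(alts), KEEP.OUT.ATTRS = FALSE)
    grid <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
    block <- matrix(1L, nrow = nrow(grid), ncol = n)
    block[, pos] <- grid
    rows[[length(rows) + 1L]] <- block
  }
  if (length(rows) == 0L) return(matrix(1L, nrow = 0L, ncol = n))
  do.call(rbind, rows)
}
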
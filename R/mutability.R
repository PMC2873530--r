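#' @importFrom utils data
NULL

# cached 20x20 BLOSUM-62 block in AMINO_ACIDS order
.deimmune_env <- new.env(parent = emptyenv())

#' The BLOSUM-62 substitution matrix (20 standard residues)
#'
#' The standard published BLOSUM-62 table, subset to the 20 amino acids in
#' [AMINO_ACIDS] order (taken from the packaged copy shipped with Biostrings).
#'
#' @return Integer 20x20 matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.deimmune_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .deimmune_env$blosum62 <- e$BLOSUM62[AMINO_ACIDS, AMINO_ACIDS]
  }
  .deimmune_env$blosum62
}

new_allowed_residues <- function(seq_res, allowed, source, penalty,
                                 penalty_type) {
  stopifnot(length(allowed) == length(seq_res))
  for (i in seq_along(allowed)) {
    if (!(seq_res[i] %in% allowed[[i]])) {
      stop("internal error: wild type missing from allowed set at position ", i)
    }
  }
  structure(
    list(
      sequence = paste(seq_res, collapse = ""),
      residues = seq_res,
      allowed = allowed,
      source = source,
      penalty = penalty,        # n x 20 matrix or NULL
      penalty_type = penalty_type
    ),
    class = "allowed_residues"
  )
}

#' @export
print.allowed_residues <- function(x, ...) {
  sizes <- lengths(x$allowed)
  cat("Allowed-residue map (", x$source, "): ", length(sizes),
      " positions, mean ", round(mean(sizes), 1),
      " residues/position (wild type included)\n", sep = "")
  invisible(x)
}

#' Sizes of the allowed sets
#' @param M An `"allowed_residues"` object.
#' @return Integer vector of per-position set sizes (wild type included).
#' @export
allowed_sizes <- function(M) {
  stopifnot(inherits(M, "allowed_residues"))
  lengths(M$allowed)
}

#' Allowed residues under the relative BLOSUM-62 rule
#'
#' A substitution wt -> a is allowed when the drop from the diagonal,
#' `B(wt, wt) - B(wt, a)`, is at most `max_diff` (default 4, a reasonably
#' conservative set). The wild type is always allowed. The companion penalty
#' table is the 0/1 "disallowed" flag summed into the B column of variant
#' reports.
#'
#' @param seq Protein sequence over the 20-letter alphabet.
#' @param max_diff Maximum allowed score drop from the diagonal (integer).
#' @return An `"allowed_residues"` object with `penalty_type = "blosum_flag"`.
#' @examples
#' M <- blosum_allowed("TAYKEFRVVELDPSAKI")
#' mean(allowed_sizes(M)) # 4.18 -> 4.2 residues/position
#' @export
blosum_allowed <- function(seq, max_diff = 4) {
  res <- as_residues(seq)
  B <- blosum62()
  n <- length(res)
  allowed <- vector("list", n)
  flag <- matrix(1, nrow = n, ncol = 20, dimnames = list(NULL, AMINO_ACIDS))
  for (i in seq_len(n)) {
    wt <- res[i]
    ok <- AMINO_ACIDS[B[wt, wt] - B[wt, ] <= max_diff]
    ok <- sort(union(ok, wt))
    allowed[[i]] <- ok
    flag[i, ok] <- 0
    flag[i, wt] <- 0
  }
  new_allowed_residues(res, allowed, "blosum", flag, "blosum_flag")
}

#' Tree-based sequence weights (bottom-up branch apportionment)
#'
#' Computes per-leaf weights that down-weight closely related sequences so
#' family frequency estimates are not dominated by redundant rows. Edges are
#' visited from the leaves toward the root; each edge's length is divided
#' among the leaves below it in proportion to their currently accumulated
#' weights (equally when all are still zero). A leaf's weight is its
#' accumulated total. A root edge, if present, is apportioned like any other
#' edge. If every branch length is zero the weights are uniform and a warning
#' is emitted.
#'
#' @param tree An [ape::read.tree()] `"phylo"` object with branch lengths.
#' @return Named numeric vector of positive weights, one per leaf label.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' gsc_weights(tr) # A = 1.5, B = 1.5, C = 2.0
#' @export
gsc_weights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  # leaves below each node
  nnode <- ntip + tr$Nnode
  below <- vector("list", nnode)
  for (v in seq_len(ntip)) below[[v]] <- v
  w <- numeric(ntip)
  # postorder edge order guarantees children edges precede parent edges
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2L]
    parent <- tr$edge[k, 1L]
    if (child > ntip && is.null(below[[child]])) {
      stop("internal error: postorder traversal out of order")
    }
    leaves <- below[[child]]
    len <- tr$edge.length[k]
    tot <- sum(w[leaves])
    if (tot == 0) {
      w[leaves] <- w[leaves] + len / length(leaves)
    } else {
      w[leaves] <- w[leaves] + len * w[leaves] / tot
    }
    below[[parent]] <- c(below[[parent]], leaves)
  }
  if (!is.null(tr$root.edge) && tr$root.edge > 0) {
    tot <- sum(w)
    if (tot == 0) w <- w + tr$root.edge / ntip
    else w <- w + tr$root.edge * w / tot
  }
  if (all(w == 0)) {
    warning("all branch lengths are zero; returning uniform weights",
            call. = FALSE)
    w <- rep(1, ntip)
  }
  stats::setNames(w, tr$tip.label)
}

#' Assemble a weighted multiple sequence alignment
#'
#' Couples an aligned family (gapped, equal-length rows) with per-sequence
#' weights and a map from target positions to alignment columns. The column
#' map is derived from the target row's non-gap columns when `target_id`
#' names a row of the alignment; otherwise supply `column_map` explicitly.
#'
#' @param alignment Named character vector of equal-length gapped sequences,
#'   or a `Biostrings::AAStringSet` (e.g. from [read_alignment_fasta()]).
#' @param weights Named positive weights per sequence id (e.g. from
#'   [gsc_weights()]). If `NULL`, uniform weights are used with a warning.
#' @param target_id Name of the target row, used both for the column map and
#'   the wild-type sequence.
#' @param column_map Optional integer vector mapping target position ->
#'   alignment column (overrides derivation from `target_id`).
#' @return An object of class `"weighted_alignment"`.
#' @export
weighted_alignment <- function(alignment, weights = NULL, target_id = NULL,
                               column_map = NULL) {
  if (inherits(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment rows must be named", call. = FALSE)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) {
    warning("no sequence weights supplied; using uniform weights",
            call. = FALSE)
    weights <- stats::setNames(rep(1, length(alignment)), names(alignment))
  }
  missing_ids <- setdiff(names(weights), names(alignment))
  if (length(missing_ids) > 0L) {
    stop("weight ids absent from the alignment: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  unweighted <- setdiff(names(alignment), names(weights))
  if (length(unweighted) > 0L) {
    stop("alignment rows without weights: ",
         paste(unweighted, collapse = ", "), call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  rows <- do.call(rbind, strsplit(alignment, ""))
  rownames(rows) <- names(alignment)
  target_res <- NULL
  if (is.null(column_map)) {
    if (is.null(target_id)) {
      stop("supply target_id or an explicit column_map", call. = FALSE)
    }
    if (!(target_id %in% names(alignment))) {
      stop("target_id ", sQuote(target_id), " is not a row of the alignment",
           call. = FALSE)
    }
    trow <- rows[target_id, ]
    column_map <- which(!(trow %in% c("-", ".")))
    target_res <- trow[column_map]
  } else if (!is.null(target_id) && target_id %in% names(alignment)) {
    target_res <- rows[target_id, column_map]
  }
  structure(
    list(rows = rows, weights = weights[names(alignment)],
         column_map = as.integer(column_map), target_id = target_id,
         target_residues = target_res),
    class = "weighted_alignment"
  )
}

#' Weighted per-column residue frequencies
#'
#' For target position `i`, the frequency of residue `a` is the total weight
#' of sequences carrying `a` in the mapped column, divided by the total
#' weight of sequences with any non-gap residue there. Frequencies over the
#' non-gap rows of a column sum to 1.
#'
#' @param walign A [weighted_alignment()].
#' @return Numeric matrix, target positions x 20 residues; rows of all-gap
#'   columns are all zero.
#' @export
weighted_frequencies <- function(walign) {
  stopifnot(inherits(walign, "weighted_alignment"))
  n <- length(walign$column_map)
  f <- matrix(0, nrow = n, ncol = 20, dimnames = list(NULL, AMINO_ACIDS))
  w <- walign$weights
  for (i in seq_len(n)) {
    col <- walign$rows[, walign$column_map[i]]
    nongap <- !(col %in% c("-", "."))
    denom <- sum(w[nongap])
    if (denom == 0) next
    for (a in unique(col[nongap])) {
      if (!(a %in% AMINO_ACIDS)) {
        stop("alignment column ", walign$column_map[i],
             " contains invalid residue ", sQuote(a), call. = FALSE)
      }
      f[i, a] <- sum(w[nongap & col == a]) / denom
    }
  }
  f
}

#' Allowed residues from tree-weighted family conservation
#'
#' A residue is allowed at a position when its weighted family frequency is
#' at least `freq_min` (default 0.05, i.e. a negative-log penalty of at most
#' -ln 0.05 = 3.00); the wild type is always allowed. The companion penalty
#' table holds `-ln f(i, a)` in natural-log units (0.01 at 99% frequency up
#' to 4.61 at 1%), capped at `-ln 1e-6` for residues absent from the family,
#' which are never allowed. All-gap columns allow only the wild type and emit
#' a warning.
#'
#' @param walign A [weighted_alignment()] whose column map covers the target.
#' @param target Optional target sequence (string); defaults to the
#'   alignment's target row.
#' @param freq_min Minimum weighted frequency for admission (default 0.05).
#' @return An `"allowed_residues"` object with
#'   `penalty_type = "conservation"`.
#' @export
conservation_allowed <- function(walign, target = NULL, freq_min = 0.05) {
  stopifnot(inherits(walign, "weighted_alignment"))
  if (is.null(target)) {
    if (is.null(walign$target_residues)) {
      stop("no target row in the alignment; supply `target`", call. = FALSE)
    }
    res <- walign$target_residues
  } else {
    res <- as_residues(target)
  }
  n <- length(res)
  if (length(walign$column_map) != n) {
    stop("column map resolves ", length(walign$column_map),
         " positions but the target has ", n, call. = FALSE)
  }
  f <- weighted_frequencies(walign)
  eps <- 1e-6
  penalty <- -log(pmax(f, eps))
  allowed <- vector("list", n)
  for (i in seq_len(n)) {
    if (all(f[i, ] == 0)) {
      warning("all-gap alignment column for target position ", i,
              "; only the wild type is allowed there", call. = FALSE)
      allowed[[i]] <- res[i]
      next
    }
    ok <- AMINO_ACIDS[f[i, ] >= freq_min - 1e-12]
    allowed[[i]] <- sort(union(ok, res[i]))
  }
  new_allowed_residues(res, allowed, "conservation", penalty, "conservation")
}

#' Allowed residues from an external ddG substitution scan
#'
#' Consumes a per-position substitution free-energy table (e.g. a position
#' scan exported from a structure-energetics tool, kcal/mol). Values are
#' re-referenced so the wild-type self entry at each position is 0; a mutant
#' is allowed when its relative ddG is at most `margin` (default 0.25
#' kcal/mol, boundary inclusive). The companion penalty table holds the
#' relative ddG values.
#'
#' @param ddg_table Data frame with columns `position`, `wt_aa`, `mut_aa`,
#'   `ddg` (see [read_ddg_table()]), one row per (position, mutant), with
#'   wild-type self rows present for every position.
#' @param seq Optional target sequence to validate positions and wild types
#'   against.
#' @param margin Maximum relative ddG for admission, kcal/mol.
#' @return An `"allowed_residues"` object with `penalty_type = "ddg"`.
#' @export
foldx_allowed <- function(ddg_table, seq = NULL, margin = 0.25) {
  need <- c("position", "wt_aa", "mut_aa", "ddg")
  if (!is.data.frame(ddg_table) || !all(need %in% names(ddg_table))) {
    stop("ddg_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ddg_table[, c("position", "mut_aa")])) {
    dup <- ddg_table[duplicated(ddg_table[, c("position", "mut_aa")]), ]
    stop("duplicate (position, residue) rows in ddG table, e.g. position ",
         dup$position[1L], " residue ", dup$mut_aa[1L], call. = FALSE)
  }
  positions <- sort(unique(ddg_table$position))
  n <- max(positions)
  if (!identical(positions, seq_len(n)) ||
      (!is.null(seq) && n != nchar(paste(as_residues(seq), collapse = "")))) {
    covered <- positions
    expected <- if (is.null(seq)) seq_len(n) else seq_len(length(as_residues(seq)))
    miss <- setdiff(expected, covered)
    if (length(miss) > 0L) {
      stop("ddG table missing position(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  # wild type per position from self rows
  res <- character(n)
  for (i in seq_len(n)) {
    sub <- ddg_table[ddg_table$position == i, ]
    self <- sub[sub$wt_aa == sub$mut_aa, ]
    if (nrow(self) != 1L) {
      stop("ddG table needs exactly one wild-type self row at position ", i,
           call. = FALSE)
    }
    res[i] <- self$wt_aa[1L]
  }
  res <- as_residues(paste(res, collapse = ""))
  if (!is.null(seq)) {
    sres <- as_residues(seq)
    if (!identical(res, sres)) {
      bad <- which(res != sres)[1L]
      stop("ddG table wild type disagrees with sequence at position ", bad,
           " (", res[bad], " vs ", sres[bad], ")", call. = FALSE)
    }
  }
  penalty <- matrix(NA_real_, nrow = n, ncol = 20,
                    dimnames = list(NULL, AMINO_ACIDS))
  allowed <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- ddg_table[ddg_table$position == i, ]
    wtval <- sub$ddg[sub$mut_aa == res[i]]
    rel <- sub$ddg - wtval
    penalty[i, sub$mut_aa] <- rel
    ok <- sub$mut_aa[rel <= margin + 1e-12]
    allowed[[i]] <- sort(union(ok, res[i]))
  }
  new_allowed_residues(res, allowed, "foldx", penalty, "ddg")
}

#' Explicit allowed-residue map
#'
#' @param seq Target sequence.
#' @param allowed List (length n) of character vectors of permitted residues;
#'   the wild type is added where missing.
#' @return An `"allowed_residues"` object with `source = "explicit"`.
#' @export
explicit_allowed <- function(seq, allowed) {
  res <- as_residues(seq)
  stopifnot(length(allowed) == length(res))
  allowed <- lapply(seq_along(allowed), function(i) {
    a <- as_residues(allowed[[i]], what = paste0("allowed[", i, "]"))
    sort(union(a, res[i]))
  })
  new_allowed_residues(res, allowed, "explicit", NULL, "none")
}

#' Intersect allowed-residue maps
#'
#' Positionwise intersection of two or more maps over the same target, with
#' the wild type always retained. Penalty tables are not merged; pass the
#' individual builders' outputs to [evaluate_variant()] for reporting.
#'
#' @param ... Two or more `"allowed_residues"` objects for the same sequence.
#' @return An `"allowed_residues"` object with `source = "intersection"`.
#' @export
intersect_allowed <- function(...) {
  maps <- list(...)
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, TRUE, "allowed_residues")))
  seqs <- vapply(maps, `[[`, "", "sequence")
  if (length(unique(seqs)) != 1L) {
    stop("allowed-residue maps are for different sequences", call. = FALSE)
  }
  res <- maps[[1L]]$residues
  allowed <- lapply(seq_along(res), function(i) {
    sets <- lapply(maps, function(m) m$allowed[[i]])
    sort(union(Reduce(intersect, sets), res[i]))
  })
  new_allowed_residues(res, allowed, "intersection", NULL, "none")
}

#' Count exact-k-substitution variants under an allowed-residue map
#'
#' The number of sequences differing from the wild type at exactly `k`
#' positions, each substituted residue drawn from the map. Computed exactly
#' as the coefficient of `x^k` in the product of `(1 + (|allowed(i)| - 1) x)`
#' over positions.
#'
#' @param M An `"allowed_residues"` object.
#' @param k Number of substitutions (>= 0).
#' @return The exact count (numeric; exact while below 2^53).
#' @export
count_variants <- function(M, k) {
  stopifnot(inherits(M, "allowed_residues"), k >= 0)
  k <- as.integer(k)
  m <- lengths(M$allowed) - 1L
  n <- length(m)
  if (k > n) return(0)
  coefs <- numeric(k + 1L)
  coefs[1L] <- 1
  for (i in seq_len(n)) {
    upper <- min(k, i)
    if (upper >= 1L) {
      js <- upper:1L
      coefs[js + 1L] <- coefs[js + 1L] + coefs[js] * m[i]
    }
  }
  coefs[k + 1L]
}

#' Enumerate exact-k-substitution variants in deterministic order
#'
#' Yields every sequence differing from the wild type at exactly `k`
#' positions once, ordered by the position subset (lexicographically
#' ascending) and then alphabetically by the substituted residues (earlier
#' positions vary slower).
#'
#' @param M An `"allowed_residues"` object.
#' @param k Number of substitutions (>= 0).
#' @param guard Refuse to enumerate more than this many sequences.
#' @return Character vector of variant sequences.
#' @export
enumerate_variants <- function(M, k, guard = 1e6) {
  stopifnot(inherits(M, "allowed_residues"), k >= 0)
  k <- as.integer(k)
  total <- count_variants(M, k)
  if (total > guard) {
    stop("enumeration size ", format(total, big.mark = ","),
         " exceeds the guard (", format(guard, big.mark = ","), ")",
         call. = FALSE)
  }
  res <- M$residues
  n <- length(res)
  if (k == 0L) return(paste(res, collapse = ""))
  if (k > n) return(character(0))
  alts <- lapply(seq_len(n), function(i) sort(setdiff(M$allowed[[i]], res[i])))
  out <- character(0)
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (pos in subsets) {
    if (any(lengths(alts[pos]) == 0L)) next
    choices <- expand.grid(rev(alts[pos]), stringsAsFactors = FALSE)
    choices <- choices[, rev(seq_len(k)), drop = FALSE] # earlier pos slower
    for (r in seq_len(nrow(choices))) {
      v <- res
      v[pos] <- as.character(unlist(choices[r, ], use.names = FALSE))
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
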
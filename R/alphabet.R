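#' The 20-letter amino acid alphabet
#'
#' Standard one-letter codes in alphabetical order. All public scoring and
#' design functions operate over this alphabet; ambiguity codes (B, J, O, U,
#' X, Z) are rejected, never silently skipped, because a skipped window would
#' silently change the total epitope count.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default HLA-DRB1 allele panel names
#'
#' The eight common HLA-DRB1 alleles that together represent the majority of
#' human populations and are the conventional panel for pocket-profile epitope
#' scoring.
#'
#' @format Character vector of length 8.
#' @export
DEFAULT_DRB1_ALLELES <- c(
  "DRB1*0101", "DRB1*0301", "DRB1*0401", "DRB1*0701",
  "DRB1*0801", "DRB1*1101", "DRB1*1301", "DRB1*1501"
)

# Split a sequence string into a validated character vector of residues.
# `what` names the argument in error messages.
as_residues <- function(seq, alphabet = AMINO_ACIDS, what = "sequence") {
  if (length(seq) == 1L && is.character(seq)) {
    res <- strsplit(seq, "")[[1]]
  } else if (is.character(seq)) {
    res <- seq
  } else {
    stop(what, " must be a character string or character vector", call. = FALSE)
  }
  bad <- setdiff(unique(res), alphabet)
  if (length(bad) > 0L) {
    stop(
      what, " contains residue(s) not in the ", length(alphabet),
      "-letter alphabet: ", paste(sQuote(bad), collapse = ", "),
      call. = FALSE
    )
  }
  res
}

# Residue characters -> 1-based indices into `alphabet`.
residue_index <- function(res, alphabet = AMINO_ACIDS) {
  match(res, alphabet)
}

# Run an expression with a temporary RNG seed, restoring caller RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
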
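#' Construct a sequence variant
#'
#' A variant couples a designed sequence with its wild type, the substitution
#' list, and the display numbering offset (the label of the first residue;
#' e.g. offset 71 makes position 9 print as 79).
#'
#' @param sequence Variant sequence (string).
#' @param wildtype Wild-type sequence (string, same length).
#' @param offset Display label of the first residue (1-based, default 1).
#' @param total_score Optional total epitope count attached by the optimizer.
#' @return An object of class `"design_variant"`.
#' @export
design_variant <- function(sequence, wildtype, offset = 1L,
                           total_score = NA_integer_) {
  v <- as_residues(sequence, what = "variant sequence")
  wt <- as_residues(wildtype, what = "wild-type sequence")
  if (length(v) != length(wt)) {
    stop("variant length ", length(v), " differs from wild-type length ",
         length(wt), call. = FALSE)
  }
  diffpos <- which(v != wt)
  structure(
    list(
      sequence = paste(v, collapse = ""),
      wildtype = paste(wt, collapse = ""),
      offset = as.integer(offset),
      substitutions = data.frame(
        position = diffpos,
        wt = wt[diffpos],
        mut = v[diffpos],
        stringsAsFactors = FALSE
      ),
      sub_count = length(diffpos),
      total_score = total_score
    ),
    class = "design_variant"
  )
}

#' @export
print.design_variant <- function(x, ...) {
  cat(dot_string(x), " (", x$sub_count, " substitution",
      if (x$sub_count != 1L) "s", sep = "")
  if (x$sub_count > 0L) cat(": ", mutation_names(x), sep = "")
  cat(")")
  if (!is.na(x$total_score)) cat("  score", x$total_score)
  cat("\n")
  invisible(x)
}

#' Dot-string display of a variant
#'
#' `'.'` marks wild-type identity; letters mark substituted residues, e.g.
#' `"........T.F......"` for V79T + L81F on a peptide numbered from 71.
#'
#' @param variant A [design_variant()].
#' @return A string the length of the sequence.
#' @export
dot_string <- function(variant) {
  stopifnot(inherits(variant, "design_variant"))
  v <- strsplit(variant$sequence, "")[[1]]
  wt <- strsplit(variant$wildtype, "")[[1]]
  out <- ifelse(v == wt, ".", v)
  paste(out, collapse = "")
}

#' Parse a dot-string into a variant
#'
#' Inverse of [dot_string()]: `parse_dot_string(dot_string(v), wt, offset)`
#' reproduces `v`.
#'
#' @param text Dot-string, same length as the wild type; characters are `'.'`
#'   or residues.
#' @param wildtype Wild-type sequence.
#' @param offset Display numbering offset of the first residue.
#' @return A [design_variant()].
#' @export
parse_dot_string <- function(text, wildtype, offset = 1L) {
  wt <- as_residues(wildtype, what = "wild-type sequence")
  ch <- strsplit(text, "")[[1]]
  if (length(ch) != length(wt)) {
    stop("dot-string length ", length(ch), " differs from wild-type length ",
         length(wt), call. = FALSE)
  }
  bad <- setdiff(unique(ch), c(".", AMINO_ACIDS))
  if (length(bad) > 0L) {
    stop("dot-string contains invalid character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  v <- ifelse(ch == ".", wt, ch)
  design_variant(paste(v, collapse = ""), paste(wt, collapse = ""),
                 offset = offset)
}

#' Mutation-list display of a variant
#'
#' Offset-aware names such as `"V27T,S84E"`: wild-type residue, display
#' position (first residue = `offset`), mutant residue.
#'
#' @param variant A [design_variant()].
#' @return A comma-separated string; `""` for the identity variant.
#' @export
mutation_names <- function(variant) {
  stopifnot(inherits(variant, "design_variant"))
  s <- variant$substitutions
  if (nrow(s) == 0L) return("")
  paste0(s$wt, s$position + variant$offset - 1L, s$mut, collapse = ",")
}

#' Parse a mutation list into a variant
#'
#' Inverse of [mutation_names()] for strings like `"V27T,S84E"`.
#'
#' @param text Comma-separated mutation names (or `""` for the wild type).
#' @param wildtype Wild-type sequence.
#' @param offset Display numbering offset of the first residue.
#' @return A [design_variant()].
#' @export
parse_mutations <- function(text, wildtype, offset = 1L) {
  wt <- as_residues(wildtype, what = "wild-type sequence")
  v <- wt
  text <- trimws(text)
  if (nzchar(text)) {
    for (tok in strsplit(text, ",", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z])$", tok))[[1]]
      if (length(m) != 4L) {
        stop("malformed mutation name: ", sQuote(tok), call. = FALSE)
      }
      pos <- as.integer(m[3L]) - offset + 1L
      if (pos < 1L || pos > length(wt)) {
        stop("mutation ", sQuote(tok), " is outside the sequence (positions ",
             offset, "..", offset + length(wt) - 1L, ")", call. = FALSE)
      }
      if (wt[pos] != m[2L]) {
        stop("mutation ", sQuote(tok), " names wild type ", m[2L],
             " but the sequence has ", wt[pos], " at position ",
             offset + pos - 1L, call. = FALSE)
      }
      v[pos] <- as_residues(m[4L], what = "mutant residue")
    }
  }
  design_variant(paste(v, collapse = ""), paste(wt, collapse = ""),
                 offset = offset)
}
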
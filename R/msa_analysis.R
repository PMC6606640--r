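#' Map a human-sequence position to its alignment column
#'
#' The human row of an ortholog alignment usually contains gaps, so the
#' 1-based position of a residue in the human protein differs from the index
#' of the alignment column that holds it. This returns the column holding
#' the `pos`-th non-gap character of the human row. All column indices in
#' this package are 1-based.
#'
#' @param aln An `ortholog_alignment`.
#' @param pos 1-based position in the ungapped human sequence.
#' @return 1-based alignment column index (vectorized over `pos`).
#' @examples
#' aln <- ortholog_alignment(c("HUMAN", "MOUSE"), c("A-CD", "AQCD"), "HUMAN")
#' map_position_to_column(aln, 2)  # the 'C', column 3
#' @export
map_position_to_column <- function(aln, pos) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  pos <- as.integer(pos)
  chars <- strsplit(aln$seqs[[aln$human_index]], "")[[1L]]
  residue_cols <- which(!is_gap(chars))
  bad <- is.na(pos) | pos < 1L | pos > length(residue_cols)
  if (any(bad)) {
    stop("position(s) outside the human ungapped length (",
         length(residue_cols), "): ",
         paste(utils::head(pos[bad], 5L), collapse = ", "))
  }
  residue_cols[pos]
}

#' Amino-acid profile of an alignment column
#'
#' Counts residue occurrences in one column across all rows of the
#' alignment, human row included. Gaps (`-`, `.`) and non-canonical letters
#' (X, B, Z, U, ...) are excluded from the counts and from `n_nongap`.
#'
#' @param aln An `ortholog_alignment`.
#' @param column 1-based column index.
#' @return A `column_profile` object: list with `column` (1-based index),
#'   `counts` (named integer vector over observed residues), `n_nongap`,
#'   and `frequencies` (counts / n_nongap; empty when the column is all
#'   gaps).
#' @export
column_profile <- function(aln, column) {
  res <- residues_at_column(aln, column)
  counted <- res[res %in% AA_CANONICAL]
  counts <- table(factor(counted, levels = AA_CANONICAL))
  counts <- counts[counts > 0L]
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  structure(list(column = as.integer(column),
                 counts = counts,
                 n_nongap = n,
                 frequencies = if (n > 0L) counts / n else numeric(0)),
            class = "column_profile")
}

#' Build a column profile from explicit residue counts
#'
#' Convenience constructor for computing entropies of hypothetical columns
#' (e.g. a uniform column over all 20 amino acids) without an alignment.
#'
#' @param counts Named integer vector, names drawn from the canonical
#'   amino-acid letters.
#' @return A `column_profile` object.
#' @examples
#' shannon_entropy(profile_from_counts(setNames(rep(1, 20), c(
#'   "A","R","N","D","C","Q","E","G","H","I",
#'   "L","K","M","F","P","S","T","W","Y","V"))))
#' @export
profile_from_counts <- function(counts) {
  stopifnot(!is.null(names(counts)), all(names(counts) %in% AA_CANONICAL),
            all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0L]
  n <- sum(counts)
  structure(list(column = NA_integer_, counts = counts, n_nongap = n,
                 frequencies = if (n > 0L) counts / n else numeric(0)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat("Column profile (column ", x$column, "): n_nongap = ", x$n_nongap,
      "\n", sep = "")
  if (x$n_nongap > 0L) print(x$counts)
  invisible(x)
}

#' Shannon entropy of an alignment column
#'
#' Conservation score of a column: `-sum(p_i * log2(p_i))` over the
#' amino-acid frequencies `p_i` at the column (gaps excluded). Ranges from 0
#' (fully conserved) to `log2(20) ~ 4.322` bits (all 20 residues equally
#' frequent); low values indicate strong structural/functional constraint at
#' the position.
#'
#' @param profile A `column_profile` with `n_nongap >= 1`.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(profile) {
  stopifnot(inherits(profile, "column_profile"))
  if (profile$n_nongap < 1L) {
    stop("entropy is undefined for an all-gap column (n_nongap = 0)")
  }
  p <- profile$frequencies
  -sum(p * log2(p))
}

#' Residues of all species at one alignment column
#'
#' @param aln An `ortholog_alignment`.
#' @param column 1-based column index.
#' @return Named character vector (one entry per row, human included);
#'   gap characters are returned as-is.
#' @export
residues_at_column <- function(aln, column) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L ||
      column > aln_width(aln)) {
    stop("column index out of range [1, ", aln_width(aln), "]: ", column)
  }
  stats::setNames(toupper(substring(aln$seqs, column, column)), aln$ids)
}

#' Entropy profile of a whole alignment
#'
#' Per-column Shannon entropy over all alignment columns; all-gap columns
#' yield `NA`.
#'
#' @param aln An `ortholog_alignment`.
#' @return Numeric vector of length `aln_width(aln)`.
#' @export
entropy_profile <- function(aln) {
  vapply(seq_len(aln_width(aln)), function(j) {
    pr <- column_profile(aln, j)
    if (pr$n_nongap == 0L) NA_real_ else shannon_entropy(pr)
  }, numeric(1))
}
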
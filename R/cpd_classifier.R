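#' Classify one missense variant as compensated (CPD) or not
#'
#' A pathogenic missense variant is a compensated pathogenic deviation (CPD)
#' when its mutant residue is the native residue of at least one non-human
#' species at the same alignment column — the existential criterion: one
#' supporting species suffices. Matching is exact single-letter equality,
#' case-insensitive; gaps never match; the human row never counts as
#' support.
#'
#' If the human row's residue at the mapped column differs from the
#' variant's annotated wild-type residue, the call is still emitted but
#' flagged (`human_residue_check = "mismatch"`) with a warning; such calls
#' are excluded from downstream statistics by default.
#'
#' @param variant A one-row variant `data.frame` (columns `gene`, `wt`,
#'   `pos`, `mut`, optionally `severity`) or a list with those elements.
#' @param aln An `ortholog_alignment` for the variant's gene.
#' @return A `compensation_call`: list with `gene`, `wt`, `pos`, `mut`,
#'   `severity`, `is_cpd` (logical), `supporting_species` (character vector
#'   of non-human rows carrying the mutant residue), `column` (1-based
#'   alignment column) and `human_residue_check` (`"match"`/`"mismatch"`).
#' @export
classify_variant <- function(variant, aln) {
  v <- as.list(variant)
  column <- map_position_to_column(aln, v$pos)
  res <- residues_at_column(aln, column)
  human_res <- res[[aln$human_index]]
  check <- if (identical(human_res, toupper(v$wt))) "match" else "mismatch"
  if (check == "mismatch") {
    warning("human residue '", human_res, "' at position ", v$pos,
            " does not match annotated wild-type '", v$wt, "' (",
            v$gene, " ", v$wt, v$pos, v$mut, ")")
  }
  nonhuman <- res[-aln$human_index]
  if (length(nonhuman) == 0L) {
    warning("alignment has no non-human rows; compensation cannot be assessed")
  }
  support <- names(nonhuman)[nonhuman == toupper(v$mut)]
  structure(list(gene = v$gene, wt = toupper(v$wt), pos = as.integer(v$pos),
                 mut = toupper(v$mut),
                 severity = if (!is.null(v$severity))
                   as.character(v$severity) else "unknown",
                 is_cpd = length(support) > 0L,
                 supporting_species = support,
                 column = column,
                 human_residue_check = check),
            class = "compensation_call")
}

#' @export
print.compensation_call <- function(x, ...) {
  cat(x$gene, " ", x$wt, x$pos, x$mut, ": ",
      if (x$is_cpd) "CPD" else "noCPD", sep = "")
  if (x$is_cpd) {
    cat(" (supported by ", paste(x$supporting_species, collapse = ", "), ")",
        sep = "")
  }
  if (x$human_residue_check == "mismatch") cat(" [wt mismatch]")
  cat("\n")
  invisible(x)
}

#' Classify a full variant table against per-gene alignments
#'
#' Runs [classify_variant()] for every row of a variant table, looking up
#' the ortholog alignment of each variant's gene. Order-preserving; a
#' summary of the call counts is reported via `message()`.
#'
#' @param variants A variant `data.frame` (see [read_variant_table()]).
#' @param alignments Named list of `ortholog_alignment` objects, names are
#'   gene symbols. Every gene present in `variants` must have an entry.
#' @return A `data.frame` of calls, one row per variant, with columns
#'   `gene`, `wt`, `pos`, `mut`, `severity`, `pathogenicity`, `is_cpd`,
#'   `n_supporting`, `supporting_species` (comma-joined), `column` (1-based)
#'   and `wt_check`. Carries over a `curated` column when present.
#' @export
classify_dataset <- function(variants, alignments) {
  if (nrow(variants) == 0L) {
    return(data.frame(gene = character(), wt = character(), pos = integer(),
                      mut = character(), severity = character(),
                      pathogenicity = character(), is_cpd = logical(),
                      n_supporting = integer(),
                      supporting_species = character(), column = integer(),
                      wt_check = character(), stringsAsFactors = FALSE))
  }
  missing_genes <- setdiff(unique(variants$gene), names(alignments))
  if (length(missing_genes) > 0L) {
    stop("no alignment provided for gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  calls <- lapply(seq_len(nrow(variants)), function(i) {
    classify_variant(variants[i, , drop = FALSE],
                     alignments[[variants$gene[i]]])
  })
  out <- data.frame(
    gene = vapply(calls, `[[`, "", "gene"),
    wt = vapply(calls, `[[`, "", "wt"),
    pos = vapply(calls, `[[`, 0L, "pos"),
    mut = vapply(calls, `[[`, "", "mut"),
    severity = vapply(calls, `[[`, "", "severity"),
    pathogenicity = if ("pathogenicity" %in% names(variants))
      as.character(variants$pathogenicity) else "unknown",
    is_cpd = vapply(calls, `[[`, FALSE, "is_cpd"),
    n_supporting = vapply(calls, function(x) length(x$supporting_species), 0L),
    supporting_species = vapply(calls, function(x)
      paste(x$supporting_species, collapse = ","), ""),
    column = vapply(calls, `[[`, 0L, "column"),
    wt_check = vapply(calls, `[[`, "", "human_residue_check"),
    stringsAsFactors = FALSE)
  if ("curated" %in% names(variants)) out$curated <- variants$curated
  message(sum(out$is_cpd), " CPD / ", sum(!out$is_cpd), " noCPD calls (",
          sum(out$wt_check == "mismatch"), " flagged wild-type mismatches)")
  out
}

#' Severity-by-compensation contingency table
#'
#' Cross-tabulates calls into the 2x2 used for the severity association
#' test: rows CPD/noCPD, columns mild/severe. Calls with unknown severity
#' are excluded (with a message); calls flagged as wild-type mismatches are
#' excluded by default.
#'
#' @param calls Call `data.frame` from [classify_dataset()].
#' @param drop_mismatches Exclude calls whose human-row residue did not
#'   match the annotated wild type (default `TRUE`).
#' @param curated_only Restrict to rows with `curated == TRUE` (requires a
#'   `curated` column).
#' @return A 2x2 integer matrix, rows `c("CPD", "noCPD")`, columns
#'   `c("mild", "severe")`.
#' @examples
#' tab <- matrix(c(87, 406, 35, 443), 2,
#'               dimnames = list(c("CPD", "noCPD"), c("mild", "severe")))
#' severe_fraction(tab, "CPD")  # 29 (% of FVIII CPDs with severe disease)
#' @export
severity_contingency <- function(calls, drop_mismatches = TRUE,
                                 curated_only = FALSE) {
  if (curated_only) {
    if (!"curated" %in% names(calls)) {
      stop("curated_only = TRUE but calls have no 'curated' column")
    }
    calls <- calls[!is.na(calls$curated) & calls$curated, , drop = FALSE]
  }
  if (drop_mismatches && "wt_check" %in% names(calls)) {
    calls <- calls[calls$wt_check != "mismatch", , drop = FALSE]
  }
  known <- calls$severity %in% c("mild", "severe")
  if (any(!known)) {
    message("excluding ", sum(!known), " call(s) with unknown severity")
  }
  if (!any(known)) warning("no calls with known severity; table is all zero")
  calls <- calls[known, , drop = FALSE]
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("CPD", "noCPD"), c("mild", "severe")))
  for (grp in c(TRUE, FALSE)) {
    for (sev in c("mild", "severe")) {
      tab[if (grp) "CPD" else "noCPD", sev] <-
        sum(calls$is_cpd == grp & calls$severity == sev)
    }
  }
  tab
}

#' Percentage of severe cases in a compensation group
#'
#' `100 * severe / (mild + severe)` for the chosen row of the contingency
#' table, rounded half-up to an integer percentage (the convention used for
#' the reported per-group severe fractions).
#'
#' @param counts 2x2 contingency matrix from [severity_contingency()].
#' @param group `"CPD"` or `"noCPD"`.
#' @return Integer percentage.
#' @export
severe_fraction <- function(counts, group = c("CPD", "noCPD")) {
  group <- match.arg(group)
  row <- counts[group, ]
  n <- sum(row)
  if (n == 0L) stop("severe fraction undefined: no ", group,
                    " calls with known severity")
  floor(100 * row[["severe"]] / n + 0.5)
}
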
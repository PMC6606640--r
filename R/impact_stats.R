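#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell of a 2x2 table follows a
#' hypergeometric distribution. The two-sided p-value is the sum of the
#' probabilities of every margin-preserving table whose point probability
#' does not exceed that of the observed table (the minimum-likelihood rule,
#' with a relative tolerance of 1e-7 on the comparison to absorb floating
#' point noise in ties). Degenerate tables (a zero row or column margin)
#' carry no information and return p = 1 with a warning.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   counts.
#' @return A `cpd_test` object: list with `method`, `statistic` (sample
#'   odds ratio), `p_value`, `group_sizes` (row sums) and `medians`
#'   (`NULL` for Fisher's test).
#' @examples
#' fisher_exact_2x2(matrix(c(87, 406, 35, 443), 2))  # FVIII severity table
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(is.na(m)) || any(m < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  m <- round(m)
  a <- m[1L, 1L]
  r1 <- sum(m[1L, ]); r2 <- sum(m[2L, ])
  c1 <- sum(m[, 1L]); n <- sum(m)
  p <- if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    warning("degenerate margins: no association can be tested; p = 1")
    1
  } else {
    support <- max(0, c1 - r2):min(c1, r1)
    probs <- stats::dhyper(support, r1, r2, c1)
    obs <- stats::dhyper(a, r1, r2, c1)
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
  or <- (m[1L, 1L] * m[2L, 2L]) / (m[1L, 2L] * m[2L, 1L])
  new_cpd_test("fisher_exact", statistic = or, p_value = p,
               group_sizes = c(r1, r2))
}

new_cpd_test <- function(method, statistic, p_value, group_sizes,
                         medians = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, group_sizes = group_sizes,
                 medians = medians),
            class = "cpd_test")
}

#' @export
print.cpd_test <- function(x, ...) {
  cat(switch(x$method,
             fisher_exact = "Fisher's exact test",
             moods_median = "Mood's median test"),
      " (n = ", paste(x$group_sizes, collapse = "/"), ")\n", sep = "")
  if (!is.null(x$medians)) {
    cat("group medians: ", paste(signif(x$medians, 4), collapse = " vs "),
        "\n", sep = "")
  }
  cat("p-value = ", format(signif(x$p_value, 2)), "\n", sep = "")
  invisible(x)
}

#' Mood's median test for two samples
#'
#' Nonparametric test of equal medians: the two samples are pooled, their
#' grand median computed, each observation dichotomized into above versus
#' not-above the grand median (ties with the grand median count as "<=
#' median"), and the resulting 2x2 table tested. The default backend is the
#' exact Fisher test, which remains honest for small samples; a Pearson
#' chi-square without continuity correction is available via
#' `backend = "chisq"`.
#'
#' If every pooled value equals the grand median no dichotomy exists and
#' p = 1 is returned with a warning.
#'
#' @param x,y Numeric samples (each of length >= 1, NAs removed).
#' @param backend `"exact"` (default) or `"chisq"`.
#' @return A `cpd_test` with `method = "moods_median"`, `medians` the two
#'   group medians, `statistic` the backend statistic (odds ratio or
#'   chi-square).
#' @export
moods_median_test <- function(x, y, backend = c("exact", "chisq")) {
  backend <- match.arg(backend)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must contain at least one non-missing value")
  }
  pooled <- c(x, y)
  grand <- stats::median(pooled)
  above <- cbind(sum(x > grand), sum(y > grand))
  below <- cbind(sum(x <= grand), sum(y <= grand))
  tab <- rbind(above, below)  # rows: > median, <= median; cols: x, y
  meds <- c(stats::median(x), stats::median(y))
  if (all(pooled == grand)) {
    warning("all pooled values equal the grand median; p = 1")
    return(new_cpd_test("moods_median", statistic = NA_real_, p_value = 1,
                        group_sizes = c(length(x), length(y)),
                        medians = meds))
  }
  res <- if (backend == "exact") {
    fisher_exact_2x2(t(tab))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    new_cpd_test("moods_median", statistic = unname(ct$statistic),
                 p_value = ct$p.value, group_sizes = c(length(x), length(y)))
  }
  new_cpd_test("moods_median", statistic = res$statistic,
               p_value = res$p_value,
               group_sizes = c(length(x), length(y)), medians = meds)
}

#' Attach molecular-impact properties to compensation calls
#'
#' Builds the per-variant impact table behind the CPD/noCPD and mild/severe
#' comparisons. The stability change (ddg, kcal/mol, destabilizing
#' positive) and relative solvent accessibility (rsa, percent) come from an
#' external property table keyed by (gene, wt, pos, mut) — typically the
#' output of structure-based tools run beforehand. The BLOSUM62 score and
#' the Shannon entropy of the variant's alignment column are computed
#' internally. Variants absent from the property table keep `NA` for ddg
#' and rsa and are excluded pairwise from tests on those properties.
#'
#' @param calls Call `data.frame` from [classify_dataset()].
#' @param props `data.frame` with columns `gene`, `wt`, `pos`, `mut` and
#'   any of `ddg`, `rsa`. Keys must be unique.
#' @param alignments Named list of `ortholog_alignment` objects per gene.
#' @return `calls` with added numeric columns `ddg`, `rsa`, `blosum`,
#'   `entropy`.
#' @export
build_impact_table <- function(calls, props, alignments) {
  if (nrow(calls) == 0L) {
    calls$ddg <- numeric(0); calls$rsa <- numeric(0)
    calls$blosum <- integer(0); calls$entropy <- numeric(0)
    return(calls)
  }
  key <- function(d) paste(d$gene, d$wt, d$pos, d$mut, sep = "|")
  pk <- key(props)
  if (anyDuplicated(pk)) {
    stop("duplicate (gene, wt, pos, mut) key(s) in property table: ",
         paste(utils::head(unique(pk[duplicated(pk)]), 3L), collapse = "; "))
  }
  idx <- match(key(calls), pk)
  calls$ddg <- if ("ddg" %in% names(props))
    as.numeric(props$ddg)[idx] else NA_real_
  calls$rsa <- if ("rsa" %in% names(props))
    as.numeric(props$rsa)[idx] else NA_real_
  for (prop in c("ddg", "rsa")) {
    n_miss <- sum(is.na(calls[[prop]]))
    if (n_miss > 0L) {
      message(n_miss, " call(s) without ", prop,
              " value; excluded pairwise from ", prop, " tests")
    }
  }
  bad_rsa <- !is.na(calls$rsa) & (calls$rsa < 0 | calls$rsa > 100)
  if (any(bad_rsa)) {
    stop("rsa values outside [0, 100] in property table")
  }
  calls$blosum <- blosum62(calls$wt, calls$mut)
  calls$entropy <- vapply(seq_len(nrow(calls)), function(i) {
    shannon_entropy(column_profile(alignments[[calls$gene[i]]],
                                   calls$column[i]))
  }, numeric(1))
  calls
}

IMPACT_PROPERTIES <- c("ddg", "rsa", "blosum", "entropy")

extract_groups <- function(records, property, grouping) {
  vals <- records[[property]]
  keep <- !is.na(vals)
  if (grouping == "cpd") {
    g1 <- vals[keep & records$is_cpd]
    g2 <- vals[keep & !records$is_cpd]
    labels <- c("CPD", "noCPD")
  } else {
    if (!all(records$is_cpd)) {
      records <- records[records$is_cpd, , drop = FALSE]
      vals <- records[[property]]
      keep <- !is.na(vals)
    }
    g1 <- vals[keep & records$severity == "mild"]
    g2 <- vals[keep & records$severity == "severe"]
    labels <- c("mild", "severe")
  }
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("insufficient data: need >= 2 non-missing ", property,
         " values per group (", labels[1L], ": ", length(g1), ", ",
         labels[2L], ": ", length(g2), ")")
  }
  list(g1 = g1, g2 = g2, labels = labels)
}

#' Compare an impact property between CPDs and noCPDs
#'
#' Mood's median test of the chosen property between compensated and
#' non-compensated calls, after pairwise removal of missing values. The
#' first reported median belongs to the CPD group.
#'
#' @param records Impact table from [build_impact_table()].
#' @param property One of `"ddg"`, `"rsa"`, `"blosum"`, `"entropy"`.
#' @param backend Passed to [moods_median_test()].
#' @return A `cpd_test`.
#' @export
compare_cpd_vs_nocpd <- function(records,
                                 property = c("ddg", "rsa", "blosum",
                                              "entropy"),
                                 backend = c("exact", "chisq")) {
  property <- match.arg(property)
  g <- extract_groups(records, property, "cpd")
  moods_median_test(g$g1, g$g2, backend = match.arg(backend))
}

#' Compare an impact property between mild and severe CPDs
#'
#' Mood's median test of the chosen property between CPDs associated with
#' mild versus severe disease. Non-CPD records and unknown severities are
#' dropped. The first reported median belongs to the mild group.
#'
#' @inheritParams compare_cpd_vs_nocpd
#' @return A `cpd_test`.
#' @export
compare_mild_vs_severe <- function(records,
                                   property = c("ddg", "rsa", "blosum",
                                                "entropy"),
                                   backend = c("exact", "chisq")) {
  property <- match.arg(property)
  g <- extract_groups(records, property, "severity")
  moods_median_test(g$g1, g$g2, backend = match.arg(backend))
}

#' Distribution overlap: fraction of one sample below the median of another
#'
#' Quantifies how much two property distributions overlap: the percentage
#' of values in `b` strictly below the median of `a`. With identical
#' continuous distributions this is about 50%; a CPD median lying above 63%
#' of noCPD values, say, means half the CPDs are more disruptive than 63%
#' of noCPDs.
#'
#' @param a,b Numeric samples (length >= 1 after NA removal).
#' @return Percentage in [0, 100].
#' @export
overlap_fraction <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) stop("samples must be non-empty")
  100 * mean(b < stats::median(a))
}

#' Run the full battery of impact comparisons
#'
#' Convenience wrapper producing a tidy summary table of every property
#' comparison for one gene's calls: CPD vs noCPD for all four properties,
#' and mild vs severe within CPDs.
#'
#' @param records Impact table from [build_impact_table()].
#' @param backend Passed to [moods_median_test()].
#' @return `data.frame` with columns `comparison`, `property`, `n1`, `n2`,
#'   `median1`, `median2`, `p_value`.
#' @export
impact_comparison_table <- function(records, backend = c("exact", "chisq")) {
  backend <- match.arg(backend)
  rows <- list()
  for (comparison in c("cpd_vs_nocpd", "mild_vs_severe")) {
    fun <- if (comparison == "cpd_vs_nocpd") compare_cpd_vs_nocpd
           else compare_mild_vs_severe
    for (prop in IMPACT_PROPERTIES) {
      res <- tryCatch(fun(records, prop, backend = backend),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = comparison, property = prop,
        n1 = res$group_sizes[1L], n2 = res$group_sizes[2L],
        median1 = res$medians[1L], median2 = res$medians[2L],
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
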
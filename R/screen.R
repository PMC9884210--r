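#' Contingency table of counts
#'
#' @param counts Numeric matrix of non-negative counts with row and column
#'   names (categories of the tabulated variable by outcome group).
#' @return An object of class `contingency_table` wrapping the counts and
#'   their margins.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and non-negative")
  }
  if (sum(counts) <= 0) abort("table total must be positive")
  structure(list(counts = counts,
                 row_margin = rowSums(counts),
                 col_margin = colSums(counts),
                 total = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %dx%d, n = %g\n",
              nrow(x$counts), ncol(x$counts), x$total))
  print(x$counts)
  invisible(x)
}

#' Cross-tabulate a variable against the outcome group
#'
#' @param dataset Coded tibble of factors.
#' @param var Variable to tabulate (rows).
#' @param group Grouping variable (columns), usually the outcome.
#' @return A [contingency_table()]; unobserved factor states are retained
#'   as zero rows/columns.
#' @export
crosstab <- function(dataset, var, group) {
  if (identical(var, group)) abort("var and group must differ")
  for (v in c(var, group)) {
    if (!v %in% names(dataset)) abort(sprintf("no variable '%s'", v))
  }
  contingency_table(unclass(table(dataset[[var]], dataset[[group]])))
}

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) with expected counts
#' E = row x col / total and df = (r - 1)(c - 1). For 2x2 tables the Yates
#' continuity correction (|O - E| - 0.5 in the numerator) is applied by
#' default; larger tables are always uncorrected.
#'
#' @param table A [contingency_table()] (or plain count matrix).
#' @param correct Apply the continuity correction to 2x2 tables.
#' @return A one-row tibble: `statistic`, `df`, `p`, `corrected`.
#' @export
chi_square_test <- function(table, correct = TRUE) {
  if (!inherits(table, "contingency_table")) {
    table <- contingency_table(table)
  }
  m <- table$counts
  if (any(table$row_margin == 0)) {
    abort(sprintf("degenerate table: empty row '%s'",
                  rownames(m)[which(table$row_margin == 0)[1L]] %||% ""))
  }
  if (any(table$col_margin == 0)) {
    abort(sprintf("degenerate table: empty column '%s'",
                  colnames(m)[which(table$col_margin == 0)[1L]] %||% ""))
  }
  use_correction <- correct && all(dim(m) == c(2L, 2L))
  res <- suppressWarnings(stats::chisq.test(m, correct = use_correction))
  tibble::tibble(statistic = unname(res$statistic),
                 df = as.integer(unname(res$parameter)),
                 p = unname(res$p.value),
                 corrected = use_correction)
}

#' Chi-square screening of candidate risk factors
#'
#' Tests every non-outcome variable against the binary outcome and keeps
#' those with p below the significance level, the univariate filter that
#' feeds the logistic stage.
#'
#' @param dataset Coded tibble of factors.
#' @param outcome Binary outcome variable name.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param correct Continuity-correct 2x2 tables (see [chi_square_test()]).
#' @return A tibble with one row per candidate: `variable`, `statistic`,
#'   `df`, `p`, `selected`, ordered as in the dataset.
#' @export
screen_variables <- function(dataset, outcome, alpha = 0.05, correct = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  if (!outcome %in% names(dataset)) abort(sprintf("no variable '%s'", outcome))
  if (nlevels(droplevels(dataset[[outcome]])) != 2L) {
    abort("outcome must be binary")
  }
  vars <- setdiff(names(dataset), outcome)
  res <- purrr::map_dfr(vars, function(v) {
    tab <- crosstab(dataset, v, outcome)
    keep <- tab$row_margin > 0          # drop unobserved states for testing
    tst <- chi_square_test(contingency_table(tab$counts[keep, , drop = FALSE]),
                           correct = correct)
    dplyr::mutate(tst, variable = v, .before = 1L)
  })
  dplyr::mutate(res, selected = .data$p < alpha)
}
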
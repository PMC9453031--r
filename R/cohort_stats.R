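#' Two-sample t-test on two numeric vectors
#'
#' Thin, validated front-end for the group-comparison battery. Welch's
#' unequal-variance form is the default; `welch = FALSE` selects the
#' classical pooled-variance test. Non-finite values are dropped within
#' each sample. If both samples are constant (zero variance in both
#' groups) the test statistic is undefined; the battery then reports
#' p = 1 with a warning instead of aborting mid-run.
#'
#' @param x,y Numeric vectors, each with at least two finite values.
#' @param welch Use the Welch unequal-variance form (default `TRUE`).
#' @param variable Optional name used in error messages.
#' @return List with `statistic`, `p`, `df`, `method`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6), welch = FALSE)
#' @export
two_sample_t <- function(x, y, welch = TRUE, variable = NULL) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  lab <- variable %||% "x/y"
  if (length(x) < 2L || length(y) < 2L)
    stop_mal(sprintf("variable %s: each group needs >= 2 finite values", lab),
             "insufficient_data_error")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning(sprintf("variable %s: zero variance in both groups; reporting p = 1", lab))
    return(list(statistic = NA_real_, p = 1, df = NA_real_,
                method = "degenerate (zero variance in both groups)"))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       method = if (welch) "Welch two-sample t" else "pooled two-sample t")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test with the standard definition: the p-value is the
#' sum of hypergeometric probabilities, over tables with the observed
#' margins, of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts, total >= 1.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_mal("table must be 2x2", "validation_error")
  if (any(is.na(table)) || any(table < 0) || any(table != floor(table)))
    stop_mal("table entries must be non-negative integers", "validation_error")
  if (sum(table) < 1)
    stop_mal("table must contain at least one observation", "validation_error")
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values))
    stop_mal("p_values must be numeric", "validation_error")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_mal("p-values must lie in [0, 1]", "validation_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Define one variable of the group-comparison battery
#'
#' @param variable Column name in the labelled cohort.
#' @param kind `"continuous"` (t-test), `"binary"` (Fisher exact) or
#'   `"categorical"` (expanded into one-vs-rest binary tests per level).
#' @param summary Summary style: `"mean_sd"`, `"median_iqr"` (continuous)
#'   or `"proportion"` (binary/categorical; forced for those kinds).
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(variable,
                            kind = c("continuous", "binary", "categorical"),
                            summary = NULL) {
  kind <- match.arg(kind)
  summary <- if (kind == "continuous") {
    match.arg(summary %||% "mean_sd", c("mean_sd", "median_iqr"))
  } else "proportion"
  structure(list(variable = variable, kind = kind, summary = summary),
            class = "comparison_spec")
}

#' The default clinical comparison battery
#'
#' Mirrors the standard single-vs-multiple-lesion characteristics table:
#' age, sex, comorbidities and vascular risk factors, stroke etiology
#' (one-vs-rest per category), DWI lesion volume, WMH burden, NIHSS and
#' mRS.
#'
#' @return List of [comparison_spec()] objects.
#' @export
default_battery <- function() {
  list(
    comparison_spec("age", "continuous", "mean_sd"),
    comparison_spec("sex", "binary"),
    comparison_spec("htn", "binary"),
    comparison_spec("dm", "binary"),
    comparison_spec("af", "binary"),
    comparison_spec("cad", "binary"),
    comparison_spec("smoker", "binary"),
    comparison_spec("etiology", "categorical"),
    comparison_spec("dwi_vol_ml", "continuous", "median_iqr"),
    comparison_spec("wmh_vol_ml", "continuous", "median_iqr"),
    comparison_spec("nihss", "continuous", "mean_sd"),
    comparison_spec("mrs", "continuous", "median_iqr")
  )
}

summarize_values <- function(x, style) {
  switch(style,
         mean_sd = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
         median_iqr = sprintf("%.1f (%.1f)", stats::median(x), stats::IQR(x)),
         proportion = sprintf("%.1f%%", 100 * mean(x)))
}

#' Compare clinical characteristics between single- and multiple-lesion patients
#'
#' Runs the comparison battery on a labelled cohort: two-sample t-tests
#' for continuous variables, Fisher's exact tests for binary variables,
#' one-vs-rest Fisher tests for each level of a categorical variable.
#' Raw p-values are FDR-adjusted jointly across the whole battery
#' (Benjamini-Hochberg); significance is declared at adjusted p < 0.05.
#' Each variable is analysed on its complete cases, and the analysed group
#' sizes are reported per variable.
#'
#' @param cohort Labelled cohort (must contain the grouping column).
#' @param specs List of [comparison_spec()]s; defaults to [default_battery()].
#' @param group Name of the logical grouping column; `TRUE` = multiple
#'   lesions. Default `"mal"`.
#' @param welch Passed to [two_sample_t()].
#' @return Data frame of class `comparison_battery` with one row per test:
#'   `variable`, `n_single`, `n_multiple`, `summary_single`,
#'   `summary_multiple`, `test`, `statistic`, `p_raw`, `p_fdr`,
#'   `significant`.
#' @export
compare_groups <- function(cohort, specs = default_battery(), group = "mal",
                           welch = TRUE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_mal("cohort must be a non-empty data frame", "empty_input_error")
  if (!group %in% names(cohort))
    stop_mal(sprintf("grouping column `%s` not found; run classify_cohort() first", group),
             "configuration_error")
  if (length(specs) < 1L)
    stop_mal("at least one comparison spec is required", "configuration_error")
  g <- as.logical(cohort[[group]])
  rows <- list()
  for (spec in specs) {
    v <- spec$variable
    if (!v %in% names(cohort))
      stop_mal(sprintf("unknown variable `%s` in comparison battery", v),
               "configuration_error")
    val <- cohort[[v]]
    keep <- !is.na(val) & !is.na(g)
    x1 <- val[keep & !g]   # single-lesion group
    x2 <- val[keep & g]    # multiple-lesion group
    if (spec$kind == "continuous") {
      ht <- two_sample_t(x1, x2, welch = welch, variable = v)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, n_single = length(x1), n_multiple = length(x2),
        summary_single = summarize_values(x1, spec$summary),
        summary_multiple = summarize_values(x2, spec$summary),
        test = ht$method, statistic = ht$statistic, p_raw = ht$p,
        stringsAsFactors = FALSE)
    } else {
      levels_to_test <- if (spec$kind == "binary") list(1) else
        as.list(sort(unique(val[keep])))
      for (lev in levels_to_test) {
        b1 <- as.integer(x1 == lev)
        b2 <- as.integer(x2 == lev)
        tab <- rbind(single = c(yes = sum(b1), no = sum(1 - b1)),
                     multiple = c(yes = sum(b2), no = sum(1 - b2)))
        p <- fisher_exact_2x2(tab)
        label <- if (spec$kind == "binary") v else paste0(v, ":", lev)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = label, n_single = length(b1), n_multiple = length(b2),
          summary_single = summarize_values(b1, "proportion"),
          summary_multiple = summarize_values(b2, "proportion"),
          test = "Fisher exact", statistic = NA_real_, p_raw = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < 0.05
  attr(out, "fdr_method") <- "Benjamini-Hochberg step-up"
  class(out) <- c("comparison_battery", "data.frame")
  out
}
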
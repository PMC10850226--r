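# Baseline-characteristics table and the test-selection logic: normality
# decides mean/SD vs median/IQR and Welch vs Wilcoxon; expected cell
# counts decide chi-square vs Fisher.

# Shapiro-Wilk is defined for 3..5000 observations; larger samples are
# thinned to a deterministic evenly-spaced subsample of the sorted values.
.normality_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(0)
  if (length(x) > 5000) {
    x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  }
  stats::shapiro.test(x)$p.value
}

#' Summarise a continuous variable with automatic routing
#'
#' Normally distributed variables (Shapiro-Wilk p >= 0.05) are reported as
#' mean and SD; others as median and quartiles (linear-interpolation,
#' type-7 quantiles). Constant vectors route to the nonnormal summary with
#' zero IQR.
#'
#' @param x Numeric vector (missing values dropped; at least 3 required).
#' @return A one-row tibble: `route` ("normal"/"nonnormal"), `n`, `mean`,
#'   `sd`, `median`, `q1`, `q3`, `shapiro_p`.
#' @export
summarize_continuous <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  p <- .normality_p(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    route = if (p >= 0.05) "normal" else "nonnormal",
    n = length(x), mean = mean(x), sd = stats::sd(x),
    median = q[2], q1 = q[1], q3 = q[3], shapiro_p = p
  )
}

#' Compare groups on a categorical variable with automatic test selection
#'
#' Uses the chi-square test (no continuity correction) when every expected
#' cell count is at least 5, and Fisher's exact test otherwise. Fisher on
#' tables larger than 2x2 is refused with advice to collapse categories.
#'
#' @param tab A two-way contingency table (matrix of counts).
#' @return A list with `test` ("chi_square"/"fisher"), `p`, `statistic`
#'   (chi-square only), and `expected` (the expected-count matrix).
#' @export
#' @examples
#' select_categorical_test(matrix(c(20, 20, 20, 20), 2))
select_categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), length(dim(tab)) == 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(test = "chi_square", p = ct$p.value,
         statistic = unname(ct$statistic), expected = expected)
  } else {
    if (any(dim(tab) > 2)) {
      stop("expected count < 5 on a table larger than 2x2; collapse ",
           "categories before testing", call. = FALSE)
    }
    ft <- stats::fisher.test(tab)
    list(test = "fisher", p = ft$p.value, statistic = NA_real_,
         expected = expected)
  }
}

#' Compare groups on a continuous variable with automatic test selection
#'
#' Welch's unequal-variance t-test when both groups pass the Shapiro-Wilk
#' normality check at 0.05; otherwise the Wilcoxon rank-sum test with the
#' tie-corrected normal approximation.
#'
#' @param x,y Numeric vectors for the two groups (>= 3 non-missing each).
#' @return A list with `test` ("welch_t"/"wilcoxon"), `p`, and
#'   `statistic` (t, or the rank-sum W).
#' @export
select_continuous_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("each group needs at least 3 non-missing values", call. = FALSE)
  }
  if (.normality_p(x) >= 0.05 && .normality_p(y) >= 0.05) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(test = "welch_t", p = tt$p.value, statistic = unname(tt$statistic))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    list(test = "wilcoxon", p = wt$p.value, statistic = unname(wt$statistic))
  }
}

#' Baseline-characteristics table
#'
#' One row per variable level, mirroring the usual "Table 1" layout:
#' counts with percentages for categoricals, mean (SD) or median (Q1, Q3)
#' for continuous variables depending on the normality route. When a
#' two-level `by` variable is supplied, the appropriate comparison test is
#' chosen per variable (off by default).
#'
#' @param data Cohort tibble.
#' @param variables Character vector of columns to summarise (defaults to
#'   the standard demographic/clinical set present in `data`).
#' @param by Optional name of a two-level grouping column; adds a test
#'   name and p-value per variable.
#' @return A tibble with `variable`, `level`, `summary`, and (with `by`)
#'   `test` and `p`.
#' @export
baseline_table <- function(data, variables = NULL, by = NULL) {
  default_vars <- c("age", "sex", "race", "smoking", "nihss", "fi",
                    "mrs_90d", "composite", "death")
  variables <- variables %||% intersect(default_vars, names(data))
  fmt_cont <- function(s) {
    if (s$route == "normal") {
      sprintf("%.1f (%.1f)", s$mean, s$sd)
    } else {
      sprintf("%.2f (%.2f, %.2f)", s$median, s$q1, s$q3)
    }
  }
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      s <- summarize_continuous(x)
      res <- tibble::tibble(variable = v, level = s$route,
                            summary = fmt_cont(s))
      if (!is.null(by)) {
        g <- data[[by]]
        ct <- select_continuous_test(x[g == levels(factor(g))[1]],
                                     x[g == levels(factor(g))[2]])
        res$test <- ct$test; res$p <- ct$p
      }
      res
    } else {
      x <- factor(x)
      tab <- table(x)
      res <- tibble::tibble(
        variable = v, level = names(tab),
        summary = sprintf("%d (%.1f%%)", as.integer(tab),
                          100 * as.integer(tab) / sum(tab))
      )
      if (!is.null(by)) {
        two <- table(x, factor(data[[by]]))
        ct <- select_categorical_test(two)
        res$test <- ct$test; res$p <- ct$p
      }
      res
    }
  })
  dplyr::bind_rows(rows)
}
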
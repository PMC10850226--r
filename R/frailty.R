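#' Compute a deficit-accumulation frailty index
#'
#' The frailty index is the fraction of assessed deficits that are present:
#' each item scores 1 when present and 0 when absent, and the index is the
#' ratio of the deficit count to the number of items actually assessed. An
#' individual with four deficits among forty assessed items has an index of
#' 0.1. Items with missing status are excluded from the denominator; when
#' fewer than `min_assessed_fraction` of the schema's items were assessed
#' the index is returned as missing, so the record falls to the
#' complete-case filter downstream.
#'
#' @param deficits Numeric or logical vector of deficit indicators coded
#'   1/TRUE (present), 0/FALSE (absent), `NA` (not assessed). Length must
#'   equal the schema size.
#' @param schema A `deficit_schema`; only its size is used here.
#' @param min_assessed_fraction Minimum fraction of items that must be
#'   assessed for the index to be computed (default 0.8).
#' @return A one-row tibble with `fi`, `n_present`, `n_assessed`. `fi` is
#'   `NA` when too few items were assessed.
#' @export
#' @examples
#' sch <- deficit_schema(paste0("d", 1:40))
#' compute_fi(c(rep(1, 4), rep(0, 36)), sch)$fi  # 0.1
compute_fi <- function(deficits, schema, min_assessed_fraction = 0.8) {
  n_items <- nrow(schema)
  if (length(deficits) != n_items) {
    stop(sprintf("deficit vector length (%d) does not match schema size (%d)",
                 length(deficits), n_items), call. = FALSE)
  }
  d <- as.numeric(deficits)
  if (any(!is.na(d) & !(d %in% c(0, 1)))) {
    stop("deficit indicators must be 0/1/NA", call. = FALSE)
  }
  n_assessed <- sum(!is.na(d))
  n_present <- sum(d, na.rm = TRUE)
  fi <- if (n_assessed == 0 || n_assessed / n_items < min_assessed_fraction) {
    NA_real_
  } else {
    n_present / n_assessed
  }
  tibble::tibble(fi = fi, n_present = n_present, n_assessed = n_assessed)
}

#' Append the frailty index to a cohort table
#'
#' Row-wise application of [compute_fi()] over the schema's deficit columns.
#' Adds `fi`, `fi_n_present`, `fi_n_assessed` columns. Records whose index
#' could not be computed (too many unassessed items) get `fi = NA`.
#'
#' @param data Cohort tibble containing the schema's deficit columns.
#' @param schema A `deficit_schema`.
#' @param min_assessed_fraction Passed to [compute_fi()].
#' @return `data` with the three index columns appended.
#' @export
add_frailty_index <- function(data, schema, min_assessed_fraction = 0.8) {
  missing_cols <- setdiff(schema$column, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing deficit columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  def <- as.matrix(data[, schema$column, drop = FALSE])
  storage.mode(def) <- "double"
  bad <- !is.na(def) & !(def %in% c(0, 1))
  if (any(bad)) {
    stop("deficit indicators must be 0/1/NA; offending column(s): ",
         paste(unique(colnames(def)[which(bad, arr.ind = TRUE)[, 2]]),
               collapse = ", "),
         call. = FALSE)
  }
  n_items <- nrow(schema)
  n_assessed <- rowSums(!is.na(def))
  n_present <- rowSums(def, na.rm = TRUE)
  fi <- ifelse(n_assessed > 0 & n_assessed / n_items >= min_assessed_fraction,
               n_present / n_assessed, NA_real_)
  dplyr::mutate(data, fi = fi, fi_n_present = n_present,
                fi_n_assessed = n_assessed)
}

#' Summarise the frailty-index distribution
#'
#' Median and quartiles (linear-interpolation quantiles, the type-7
#' convention), range, and histogram counts of the per-participant index.
#'
#' @param data Cohort tibble with an `fi` column, or a numeric vector of
#'   index values.
#' @param breaks Histogram break points on \[0, 1\] (default width 0.05).
#' @return A list with `n`, `median`, `q1`, `q3`, `min`, `max`, and a
#'   `histogram` tibble of bin edges and counts.
#' @export
fi_distribution <- function(data, breaks = seq(0, 1, by = 0.05)) {
  x <- if (is.data.frame(data)) data$fi else data
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no non-missing frailty-index values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(
    n = length(x),
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(x), max = max(x),
    histogram = tibble::tibble(lower = utils::head(h$breaks, -1),
                               upper = utils::tail(h$breaks, -1),
                               count = h$counts)
  )
}
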
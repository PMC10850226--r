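#' Read and validate a patient-level cohort table
#'
#' Reads one row per participant and validates it against the analysis
#' contract: `age` in years (> 18, the inclusion criterion), `sex`
#' (male/female), `race` (white/black), `smoking` (never/former/current),
#' `nihss` (admission stroke severity, 0-42), `mrs_90d` (90-day modified
#' Rankin Scale, 0-6), plus one 0/1 column per deficit in `schema`.
#' `died_90d`, when absent, is derived from `mrs_90d == 6`; a record with
#' `died_90d = TRUE` but `mrs_90d < 6` is a validation error. Unparseable
#' numeric cells become missing with a warning; missingness is never
#' imputed, it is handled downstream by [complete_cases()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A `deficit_schema` naming the deficit columns.
#' @param sep Field separator (default comma).
#' @return A validated cohort tibble with canonical column types and an
#'   `id` column (generated from row number when absent).
#' @export
read_cohort <- function(path, schema, sep = ",") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  mandatory <- c("age", "sex", "race", "smoking", "nihss", "mrs_90d")
  miss <- setdiff(c(mandatory, schema$column), names(raw))
  if (length(miss) > 0) {
    stop("cohort file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))

  num_col <- function(x, name) {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(v)
    if (any(bad)) {
      warning(sprintf("%d unparseable value(s) in '%s' set to missing",
                      sum(bad), name), call. = FALSE)
    }
    v
  }
  cat_col <- function(x, name, levels) {
    v <- tolower(trimws(x))
    v[v == ""] <- NA_character_
    bad <- !is.na(v) & !(v %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid %s label '%s' (row id %s); expected one of: %s",
                   name, v[bad][1], raw$id[bad][1],
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    factor(v, levels = levels)
  }

  out <- tibble::tibble(
    id = as.character(raw$id),
    age = num_col(raw$age, "age"),
    sex = cat_col(raw$sex, "sex", c("female", "male")),
    race = cat_col(raw$race, "race", c("black", "white")),
    smoking = cat_col(raw$smoking, "smoking", c("never", "former", "current")),
    nihss = num_col(raw$nihss, "nihss"),
    mrs_90d = num_col(raw$mrs_90d, "mrs_90d")
  )
  if ("died_90d" %in% names(raw)) {
    out$died_90d <- tolower(trimws(raw$died_90d)) %in% c("1", "true", "yes")
    out$died_90d[is.na(raw$died_90d) | trimws(raw$died_90d) == ""] <- NA
  } else {
    out$died_90d <- ifelse(is.na(out$mrs_90d), NA, out$mrs_90d == 6)
  }
  for (cc in schema$column) out[[cc]] <- num_col(raw[[cc]], cc)

  validate_cohort(out, schema)
  out
}

#' Validate a cohort tibble against the analysis contract
#'
#' @param data Cohort tibble (as produced by [read_cohort()] or
#'   [simulate_cohort()]).
#' @param schema Optional `deficit_schema`; when given, deficit columns are
#'   checked for 0/1/NA coding.
#' @return `data`, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(data, schema = NULL) {
  chk <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      stop(sprintf("%s (row id %s)", msg, data$id[which(bad)[1]]),
           call. = FALSE)
    }
  }
  chk(data$age <= 18, "age must be > 18 years")
  chk(data$mrs_90d < 0 | data$mrs_90d > 6 |
        (data$mrs_90d %% 1) != 0, "mrs_90d out of range 0-6")
  chk(data$nihss < 0 | data$nihss > 42, "nihss out of range 0-42")
  both <- !is.na(data$mrs_90d) & !is.na(data$died_90d)
  chk(both & data$died_90d & data$mrs_90d < 6,
      "died_90d = TRUE conflicts with mrs_90d < 6")
  chk(both & !data$died_90d & data$mrs_90d == 6,
      "died_90d = FALSE conflicts with mrs_90d = 6")
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema$column, names(data))
    if (length(missing_cols) > 0) {
      stop("cohort is missing deficit columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (cc in schema$column) {
      chk(!(data[[cc]] %in% c(0, 1)) & !is.na(data[[cc]]),
          sprintf("deficit column '%s' must be 0/1/NA", cc))
    }
  }
  invisible(data)
}

#' Derive the 90-day binary outcomes from the modified Rankin Scale
#'
#' Adds `composite` (1 iff mRS > 2, the disability-or-death outcome) and
#' `death` (1 iff mRS = 6, or `died_90d` when the scale itself is missing).
#' Missing mRS yields missing outcomes; nothing is imputed.
#'
#' @param data Cohort tibble with `mrs_90d` (and optionally `died_90d`).
#' @return `data` with `composite` and `death` columns (0/1/NA).
#' @export
#' @examples
#' add_outcomes(tibble::tibble(mrs_90d = c(2, 3, 6), died_90d = NA))
add_outcomes <- function(data) {
  died <- if ("died_90d" %in% names(data)) data$died_90d else NA
  dplyr::mutate(
    data,
    composite = ifelse(is.na(.data$mrs_90d), NA_real_,
                       as.numeric(.data$mrs_90d >= 3)),
    death = dplyr::case_when(
      !is.na(.data$mrs_90d) ~ as.numeric(.data$mrs_90d == 6),
      !is.na(died) ~ as.numeric(died),
      TRUE ~ NA_real_
    )
  )
}

#' Complete-case filter with an exclusion report
#'
#' Keeps exactly the records with no missing value among `required` and
#' tallies exclusions by the *first* missing variable (in the order given),
#' mirroring a participant-flow diagram. No imputation is performed
#' anywhere in the pipeline.
#'
#' @param data Cohort tibble.
#' @param required Character vector of column names that must be
#'   non-missing.
#' @return A list with `data` (the kept records) and `dropped` (a tibble
#'   of `variable`, `n_dropped`). Warns when nothing survives.
#' @export
complete_cases <- function(data, required) {
  bad <- setdiff(required, names(data))
  if (length(bad) > 0) {
    stop("unknown required variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  miss <- vapply(required, function(v) is.na(data[[v]]), logical(nrow(data)))
  miss <- matrix(miss, nrow = nrow(data))
  first_missing <- apply(miss, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  kept <- data[is.na(first_missing), , drop = FALSE]
  tally <- table(factor(required[first_missing], levels = required))
  dropped <- tibble::tibble(variable = names(tally),
                            n_dropped = as.integer(tally))
  dropped <- dropped[dropped$n_dropped > 0, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("complete-case filter removed every record", call. = FALSE)
  }
  list(data = kept, dropped = dropped)
}

#' Encode the regression design for the mediation models
#'
#' Builds the numeric design shared by the mediator and outcome
#' regressions: outcome 0/1 vector, exposure (age in years, unscaled, so
#' odds ratios are per 1-year increment), mediator (the frailty index,
#' treated strictly as continuous), and the adjustment covariates under
#' reference coding — `sex_male` (reference female), `race_white`
#' (reference black), `smoking_former` and `smoking_current` (reference
#' never), and `nihss` as a continuous column. Reference-level choice only
#' relabels coefficients; it is recorded in the object.
#'
#' @param data Complete-case cohort tibble with `fi` and the outcome column.
#' @param outcome `"composite"` (mRS > 2) or `"death"`.
#' @return A list of class `coded_design`: `y`, `exposure`, `mediator`,
#'   `covariates` (n x 5 numeric matrix), `outcome_name`, `reference_levels`,
#'   and `constant_columns` (names of zero-variance columns, for the
#'   multicollinearity / separation screens downstream).
#' @export
encode_design <- function(data, outcome = c("composite", "death")) {
  outcome <- match.arg(outcome)
  need <- c("age", "sex", "race", "smoking", "nihss", "fi", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[, need])) {
    stop("encode_design requires complete cases; run complete_cases() first",
         call. = FALSE)
  }
  covariates <- cbind(
    sex_male = as.numeric(data$sex == "male"),
    race_white = as.numeric(data$race == "white"),
    smoking_former = as.numeric(data$smoking == "former"),
    smoking_current = as.numeric(data$smoking == "current"),
    nihss = as.numeric(data$nihss)
  )
  const <- colnames(covariates)[apply(covariates, 2, function(x) {
    length(unique(x)) == 1
  })]
  if (length(const) > 0) {
    warning("constant covariate column(s): ", paste(const, collapse = ", "),
            call. = FALSE)
  }
  structure(
    list(
      y = as.numeric(data[[outcome]]),
      exposure = as.numeric(data$age),
      mediator = as.numeric(data$fi),
      covariates = covariates,
      outcome_name = outcome,
      reference_levels = c(sex = "female", race = "black", smoking = "never"),
      constant_columns = const
    ),
    class = "coded_design"
  )
}

#' Write a cohort tibble to CSV
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
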
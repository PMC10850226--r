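test_that("well-formed rows read cleanly and keep their count", {
  sch <- toy_schema(31)
  path <- write_cohort_csv(toy_raw_cohort(3))
  expect_no_warning(cohort <- read_cohort(path, sch))
  expect_equal(nrow(cohort), 3)
  expect_s3_class(cohort$sex, "factor")
})

test_that("out-of-range and conflicting values are validation errors", {
  sch <- toy_schema(31)
  df <- toy_raw_cohort(3)
  df$mrs_90d[2] <- 7
  expect_error(read_cohort(write_cohort_csv(df), sch), "0-6")

  df <- toy_raw_cohort(3)
  df$age[1] <- 17
  expect_error(read_cohort(write_cohort_csv(df), sch), "> 18")

  df <- toy_raw_cohort(3)
  df$died_90d <- c(TRUE, FALSE, TRUE)   # row 1 has mrs 1
  expect_error(read_cohort(write_cohort_csv(df), sch), "conflicts")

  df <- toy_raw_cohort(3)
  df$sex[2] <- "unknown"
  expect_error(read_cohort(write_cohort_csv(df), sch), "row id 2")

  df <- toy_raw_cohort(3)
  df$nihss <- NULL
  expect_error(read_cohort(write_cohort_csv(df), sch), "nihss")
})

test_that("unparseable cells become missing with a warning", {
  sch <- toy_schema(31)
  df <- toy_raw_cohort(3)
  df$nihss <- c("12", "not a number", "")
  expect_warning(cohort <- read_cohort(write_cohort_csv(df), sch),
                 "nihss")
  expect_true(is.na(cohort$nihss[2]))
  expect_true(is.na(cohort$nihss[3]))
})

test_that("died_90d is derived from mRS when absent", {
  sch <- toy_schema(31)
  cohort <- read_cohort(write_cohort_csv(toy_raw_cohort(3)), sch)
  expect_equal(cohort$died_90d, c(FALSE, FALSE, TRUE))
})

test_that("outcome derivation follows the mRS > 2 and death cuts", {
  out <- add_outcomes(tibble::tibble(mrs_90d = c(3, 6, 2, NA),
                                     died_90d = c(FALSE, TRUE, FALSE, NA)))
  expect_equal(out$composite, c(1, 1, 0, NA))
  expect_equal(out$death, c(0, 1, 0, NA))
})

test_that("complete-case filter drops by first missing variable and is idempotent", {
  df <- tibble::tibble(
    age = c(70, 65, NA, 80, 75),
    nihss = c(10, NA, 5, 12, 3),
    fi = c(0.1, 0.2, 0.3, NA, 0.1)
  )
  cc <- complete_cases(df, c("age", "nihss", "fi"))
  expect_equal(nrow(cc$data), 2)
  expect_equal(cc$dropped$variable, c("age", "nihss", "fi"))
  expect_equal(cc$dropped$n_dropped, c(1L, 1L, 1L))

  again <- complete_cases(cc$data, c("age", "nihss", "fi"))
  expect_identical(again$data, cc$data)
  expect_equal(nrow(again$dropped), 0)

  none <- complete_cases(df[1, ], c("age"))
  expect_identical(none$data, df[1, ])

  all_na <- tibble::tibble(mrs_90d = c(NA_real_, NA_real_))
  expect_warning(res <- complete_cases(all_na, "mrs_90d"), "every record")
  expect_equal(nrow(res$data), 0)
})

test_that("design encoding uses the documented reference levels", {
  df <- tibble::tibble(
    age = c(70, 71, 72), sex = factor(c("female", "male", "female")),
    race = factor(c("black", "white", "white")),
    smoking = factor(c("never", "former", "current")),
    nihss = c(5, 10, 15), fi = c(0.1, 0.2, 0.3),
    composite = c(0, 1, 1)
  )
  d <- encode_design(df, "composite")
  expect_equal(colnames(d$covariates),
               c("sex_male", "race_white", "smoking_former",
                 "smoking_current", "nihss"))
  expect_equal(d$covariates[1, ], c(sex_male = 0, race_white = 0,
                                    smoking_former = 0, smoking_current = 0,
                                    nihss = 5))
  expect_equal(unname(d$covariates[2, c("smoking_former", "smoking_current")]),
               c(1, 0))
  expect_equal(unname(d$covariates[3, c("smoking_former", "smoking_current")]),
               c(0, 1))
  # two records differing only in sex differ in exactly one column
  df2 <- df[c(1, 1), ]
  df2$sex <- factor(c("female", "male"), levels = c("female", "male"))
  df2$composite <- c(0, 1)
  d2 <- suppressWarnings(encode_design(df2, "composite"))
  expect_equal(sum(d2$covariates[1, ] != d2$covariates[2, ]), 1)

  expect_warning(encode_design(df[c(1, 1), ], "composite"), "constant")
  expect_error(encode_design(dplyr::mutate(df, fi = NA_real_), "composite"),
               "complete cases")
})

test_that("cohort CSV round-trip preserves the coded design", {
  sch <- toy_schema(31)
  p <- sim_params(n = 60, mediator_mode = "deficit_level", seed = 9)
  cohort <- simulate_cohort(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- add_outcomes(read_cohort(path, default_deficit_schema()))
  back <- add_frailty_index(back, default_deficit_schema())
  d1 <- encode_design(cohort, "composite")
  d2 <- encode_design(back, "composite")
  expect_equal(d2$y, d1$y)
  expect_equal(d2$exposure, d1$exposure)
  expect_equal(d2$mediator, d1$mediator)
  expect_equal(d2$covariates, d1$covariates)
})
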
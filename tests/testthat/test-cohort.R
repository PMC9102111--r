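test_that("validity filter uses inclusive wear and night thresholds", {
  days <- dplyr::bind_rows(
    make_days("boundary", wear_hours = rep(16.0, 4), valid_nights = c(TRUE, TRUE, TRUE, FALSE)),
    make_days("short_wear", wear_hours = rep(15.9, 7), valid_nights = TRUE),
    make_days("few_nights", wear_hours = rep(17, 6), valid_nights = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  )
  log <- filter_valid_participants(days)
  expect_true(log$included[log$participant_id == "boundary"])
  expect_false(log$included[log$participant_id == "short_wear"])
  expect_false(log$included[log$participant_id == "few_nights"])
  expect_equal(log$n_valid_days[log$participant_id == "short_wear"], 0)
})

test_that("a constructed 10-participant fixture includes exactly 7", {
  good <- purrr::map(1:7, ~ make_days(paste0("ok", .x), rep(17, 5), TRUE))
  bad <- list(
    make_days("fail_wear", rep(14, 7), TRUE),
    make_days("fail_days", c(17, 17, 17, 10, 10, 10, 10), TRUE),  # 3 valid days
    make_days("fail_nights", rep(17, 7), c(TRUE, TRUE, rep(FALSE, 5)))
  )
  log <- filter_valid_participants(dplyr::bind_rows(good, bad))
  expect_equal(sum(log$included), 7)
  expect_setequal(log$participant_id[!log$included],
                  c("fail_wear", "fail_days", "fail_nights"))
})

test_that("raising the wear threshold never adds participants", {
  set.seed(4)
  days <- purrr::map_dfr(1:30, function(i) {
    make_days(paste0("p", i), wear_hours = runif(7, 12, 24),
              valid_nights = runif(7) > 0.2)
  })
  prev <- NULL
  for (h in c(12, 14, 16, 18, 20)) {
    inc <- filter_valid_participants(days, min_wear_hours = h)
    ids <- inc$participant_id[inc$included]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("day averaging is an arithmetic mean closed to kappa", {
  d1 <- tibble::tibble(participant_id = "a", sleep = 400, sed = 300, lpa = 600, mvpa = 40)
  d2 <- tibble::tibble(participant_id = "a", sleep = 500, sed = 350, lpa = 500, mvpa = 90)
  avg <- average_valid_days(dplyr::bind_rows(d1, d2))
  mid <- c(sleep = 450, sed = 325, lpa = 550, mvpa = 65)
  expect_equal(unlist(avg[behaviours()]), mid * (1440 / sum(mid)),
               tolerance = 1e-12)

  # identical days come back unchanged (already a 1440 day after closure)
  same <- dplyr::bind_rows(d1, d1)
  avg2 <- average_valid_days(same)
  expect_equal(unlist(avg2[behaviours()]),
               unlist(close_composition(d1[behaviours()])), tolerance = 1e-12)

  # commutes with uniform rescaling of all days
  scaled <- dplyr::bind_rows(d1, d2) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(behaviours()), ~ .x * 3.7))
  expect_equal(average_valid_days(scaled), avg, tolerance = 1e-12)
})

test_that("zero policy replaces or rejects as configured", {
  x <- c(sleep = 480, sed = 300, lpa = 600, mvpa = 0)
  expect_message(
    out <- apply_zero_policy(x, policy = "replace", replace_value = 1),
    "replaced 1"
  )
  expect_equal(out, c(sleep = 480, sed = 300, lpa = 600, mvpa = 1))
  expect_error(apply_zero_policy(x, policy = "reject"),
               class = "moveshift_zero_part_error")
  pos <- c(sleep = 480, sed = 300, lpa = 600, mvpa = 10)
  expect_identical(apply_zero_policy(pos, "replace"), pos)
  expect_identical(apply_zero_policy(pos, "reject"), pos)
  expect_error(apply_zero_policy(c(sleep = -1, sed = 1, lpa = 1, mvpa = 1)),
               class = "moveshift_schema_error")
})

test_that("cohort CSV round-trip is lossless and schema errors name columns", {
  sim <- simulate_cohort(children_like(n = 10, seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back, sim$cohort[names(back)], tolerance = 1e-12)

  broken <- withr::local_tempfile(fileext = ".csv")
  df <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(df[setdiff(names(df), "sex")], broken)
  expect_error(read_cohort(broken), "sex")
})

test_that("day-level files round-trip through the external schema", {
  sim <- simulate_daily_records(children_like(n = 4, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily(sim$days, path)
  back <- read_daily(path)
  expect_equal(back, sim$days[names(back)], tolerance = 1e-12)
  expect_type(back$valid_night, "logical")
})

test_that("build_cohort filters, averages and joins metadata", {
  sim <- simulate_daily_records(children_like(n = 12, seed = 3,
                                              fail_fraction = 0.25))
  meta <- sim$cohort[c("participant_id", "fev1_pct_pred", "age", "sex", "genotype")]
  cohort <- build_cohort(sim$days, meta)
  expect_equal(nrow(cohort), 12 - length(sim$constructed_failers))
  expect_false(any(cohort$participant_id %in% sim$constructed_failers))
  expect_equal(rowSums(as.matrix(cohort[behaviours()])), rep(1440, nrow(cohort)),
               tolerance = 1e-9)
  expect_true(all(cohort$age_group == "child"))
})

test_that("descriptives run Welch t-tests with sensible degenerate behaviour", {
  base <- tibble::tibble(
    sleep = 480, sed = 330, lpa = 570, mvpa = 60,
    fev1_pct_pred = c(80, 85, 90, 75), age = c(10, 12, 20, 25),
    sex = c("female", "male", "female", "male"),
    age_group = c("child", "child", "adult", "adult")
  )
  # identical groups: t = 0, p = 1 for the constant behaviour columns
  d <- cohort_descriptives(base, group_by = "sex")
  expect_equal(d$t[d$variable == "sleep"], 0)
  expect_equal(d$p.value[d$variable == "sleep"], 1)

  # well-separated groups: decisive p-value
  set.seed(8)
  big <- tibble::tibble(
    sleep = 480, sed = 330, lpa = 570, mvpa = 60,
    fev1_pct_pred = c(rnorm(50, 50, 5), rnorm(50, 100, 5)),
    age = c(rnorm(50, 10, 1), rnorm(50, 30, 1)),
    age_group = rep(c("child", "adult"), each = 50)
  )
  d2 <- cohort_descriptives(big, group_by = "age_group",
                            variables = "fev1_pct_pred")
  expect_lt(d2$p.value, 1e-6)
  expect_true(d2$significant)

  expect_error(cohort_descriptives(base[1:2, ], group_by = "sex"),
               class = "moveshift_insufficient_data_error")
})

test_that("severity bands split at 70 and 40 percent predicted", {
  expect_equal(severity_band(c(71, 70, 40, 39.9)),
               c("mild", "moderate", "moderate", "severe"))
})
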
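ref_toy <- c(sleep = 500, sed = 320, lpa = 590, mvpa = 30)

test_that("reallocate moves minutes and conserves the day exactly", {
  out <- reallocate(ref_toy, "sleep", "sed", 10)
  expect_equal(out, c(sleep = 490, sed = 330, lpa = 590, mvpa = 30))
  expect_identical(sum(out), 1440)

  expect_identical(reallocate(ref_toy, "lpa", "mvpa", 0), ref_toy)

  # moving delta then reversing returns the reference bit-exactly
  there <- reallocate(ref_toy, "sed", "mvpa", 25)
  expect_identical(reallocate(there, "mvpa", "sed", 25), ref_toy)

  expect_error(reallocate(ref_toy, "mvpa", "sleep", 30),
               class = "moveshift_infeasible_error")
  expect_error(reallocate(ref_toy, "mvpa", "mvpa", 5),
               class = "moveshift_schema_error")
})

test_that("reference composition is the compositional mean, with delegation", {
  sim <- simulate_cohort(children_like(seed = 2))
  ref <- reference_composition(sim$cohort)
  expect_equal(ref, comp_mean(sim$cohort), ignore_attr = TRUE)
  expect_equal(sum(unlist(ref)), 1440, tolerance = 1e-9)

  same <- sim$cohort[rep(4, 5), ]
  expect_equal(unlist(reference_composition(same)[behaviours()]),
               unlist(sim$cohort[4, behaviours()]), tolerance = 1e-9)

  # printed-proportions reference closes to the hand-computed minutes
  ref2 <- reference_composition(c(sleep = 0.34, sed = 0.22, lpa = 0.39,
                                  mvpa = 0.02))
  expect_equal(unlist(ref2), c(sleep = 504.742268041237, sed = 326.597938144330,
                               lpa = 578.969072164948, mvpa = 29.690721649485),
               tolerance = 1e-9)
})

test_that("predicted changes follow the ilr-difference formula exactly", {
  beta <- c(2, -3, 0.5)
  cohort <- noiseless_cohort(n = 60, beta = beta, intercept = 50, seed = 11)
  fit <- fit_ilr_model(cohort, retained = "sleep")
  ref <- reference_composition(cohort)

  # zero displacement: exactly zero with a degenerate interval
  p0 <- suppressWarnings(predict_reallocation(fit, ref, "sleep", "sed", 0))
  expect_identical(p0$estimate, 0)
  expect_identical(c(p0$ci_low, p0$ci_high), c(0, 0))

  # hand-computed beta' (z_new - z_ref) oracle at several displacements
  for (d in c(5, 10, 30)) {
    est <- suppressWarnings(predict_reallocation(fit, ref, "lpa", "mvpa", d))$estimate
    z_new <- ilr_oracle(reallocate(unlist(ref), "lpa", "mvpa", d))
    z_ref <- ilr_oracle(unlist(ref))
    expect_equal(est, sum(beta * (z_new - z_ref)), tolerance = 1e-8)
  }
})

test_that("reallocation estimates and intervals are rotation invariant", {
  sim <- simulate_cohort(adults_like(seed = 13))
  ref <- reference_composition(sim$cohort)
  grids <- purrr::map(behaviours(), function(beh) {
    fit <- fit_ilr_model(sim$cohort, retained = beh)
    tibble::as_tibble(reallocation_grid(fit, ref))
  })
  for (k in 2:4) {
    expect_equal(grids[[1]]$estimate, grids[[k]]$estimate, tolerance = 1e-8)
    expect_equal(grids[[1]]$ci_low, grids[[k]]$ci_low, tolerance = 1e-8)
    expect_equal(grids[[1]]$ci_high, grids[[k]]$ci_high, tolerance = 1e-8)
  }
})

test_that("the grid has 12 ordered pairs per delta in report order", {
  sim <- simulate_cohort(adults_like(seed = 13))
  fit <- fit_ilr_model(sim$cohort)
  ref <- reference_composition(sim$cohort)
  g <- reallocation_grid(fit, ref)
  expect_equal(nrow(g), 36)
  expect_equal(anyDuplicated(g[c("from", "to", "delta")]), 0)
  expect_equal(g$from[1:9], rep("sleep", 9))
  expect_equal(g$to[c(1, 4, 7)], c("sed", "lpa", "mvpa"))
  expect_true(all(g$ci_low <= g$estimate & g$estimate <= g$ci_high,
                  na.rm = TRUE))
  # formatted table: one row per pair, one column per delta
  wide <- format_reallocation_grid(g)
  expect_equal(dim(wide), c(12, 4))
  expect_equal(wide$reallocation[1], "Sleep to SED")
})

test_that("infeasible cells are flagged, not dropped", {
  tight <- c(sleep = 500, sed = 400, lpa = 525, mvpa = 15)
  sim <- simulate_cohort(children_like(seed = 3))
  fit <- fit_ilr_model(sim$cohort)
  g <- reallocation_grid(fit, tight, deltas = c(10, 20))
  expect_equal(nrow(g), 24)
  bad <- g[g$from == "mvpa" & g$delta == 20, ]
  expect_true(all(!bad$feasible))
  expect_true(all(is.na(bad$estimate)))
  expect_true(all(g$feasible[g$from != "mvpa"]))
})

test_that("reallocation effects are asymmetric when a part is small", {
  beta <- c(2, -3, 0.5)
  cohort <- noiseless_cohort(n = 60, beta = beta, seed = 11)
  fit <- fit_ilr_model(cohort)
  ref <- c(sleep = 490, sed = 350, lpa = 570, mvpa = 30)
  fwd <- suppressWarnings(predict_reallocation(fit, ref, "lpa", "mvpa", 20))$estimate
  rev <- suppressWarnings(predict_reallocation(fit, ref, "mvpa", "lpa", 20))$estimate
  expect_gt(abs(fwd + rev), 0.01)  # not mirror images
})

test_that("stratified grids refit per stratum and track stratum truth", {
  kids <- simulate_cohort(children_like(seed = 51))$cohort
  grown <- simulate_cohort(adults_like(seed = 52))$cohort
  cohort <- dplyr::bind_rows(kids, grown)
  s <- suppressWarnings(
    stratified_grid(cohort, strata = c("age_group", "sex", "genotype"),
                    deltas = 30, min_n = 5)
  )
  expect_equal(unique(table(s$age_group, s$sex, s$genotype)["child", , ]),
               12)  # 12 rows per analysed stratum
  expect_lte(length(unique(paste(s$age_group, s$sex, s$genotype))), 8)

  # identical strata produce identical tables
  dup <- dplyr::bind_rows(
    dplyr::mutate(kids, sex = "female"),
    dplyr::mutate(kids, sex = "male")
  )
  s2 <- stratified_grid(dup, strata = "sex", deltas = 30)
  left <- s2[s2$sex == "female", setdiff(names(s2), "sex")]
  right <- s2[s2$sex == "male", setdiff(names(s2), "sex")]
  expect_equal(left, right, ignore_attr = TRUE)

  # two strata generated under different true coefficients: each stratum's
  # estimate stays within 3 SE of its own generative truth
  cfg_a <- children_like(n = 150, seed = 61, beta = c(16, -7, -5),
                         p_male = 0, noise_sd = 10)
  cfg_b <- children_like(n = 150, seed = 62, beta = c(-6, 3, 2),
                         p_male = 1, noise_sd = 10)
  mixed <- dplyr::bind_rows(simulate_cohort(cfg_a)$cohort,
                            simulate_cohort(cfg_b)$cohort)
  s3 <- stratified_grid(mixed, strata = "sex", deltas = 30)
  for (cfg in list(female = cfg_a, male = cfg_b)) {
    sx <- if (identical(cfg$p_male, 0)) "female" else "male"
    stratum <- mixed[mixed$sex == sx, ]
    row <- s3[s3$sex == sx & s3$from == "sleep" & s3$to == "sed", ]
    truth <- true_delta(cfg, "sleep", "sed", 30,
                        reference = reference_composition(stratum))
    expect_lt(abs(row$estimate - truth), 3 * row$se)
  }
})
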
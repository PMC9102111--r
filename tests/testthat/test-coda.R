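test_that("closure rescales proportionally and is idempotent", {
  x <- c(sleep = 360, sed = 360, lpa = 360, mvpa = 360)
  expect_equal(close_composition(x), x)

  # proportions summing to 0.97, closed by hand: x_i * 1440 / 0.97
  props <- c(sleep = 0.34, sed = 0.22, lpa = 0.39, mvpa = 0.02)
  expect_equal(close_composition(props),
               c(sleep = 504.742268041237, sed = 326.597938144330,
                 lpa = 578.969072164948, mvpa = 29.690721649485),
               tolerance = 1e-12)

  m <- random_comp_matrix(20, seed = 3, kappa = 7)  # arbitrary raw scale
  once <- close_composition(m)
  expect_identical(close_composition(once), once)
  expect_equal(rowSums(once), rep(1440, 20))

  df <- tibble::as_tibble(m)
  df$id <- letters[1:20]
  out <- close_composition(df)
  expect_s3_class(out, "tbl_df")
  expect_identical(out$id, df$id)  # non-behaviour columns untouched
})

test_that("zero and negative parts are rejected with the behaviour named", {
  expect_error(close_composition(c(sleep = 1, sed = 1, lpa = 1, mvpa = 0)),
               class = "moveshift_zero_part_error")
  expect_error(close_composition(c(sleep = 1, sed = 1, lpa = 1, mvpa = 0)),
               "mvpa")
  expect_error(close_composition(tibble::tibble(sleep = 1, sed = 1, lpa = 1)),
               class = "moveshift_schema_error")
})

test_that("pivot bases match the definition and are orthonormal", {
  b <- pivot_basis()
  a <- sqrt(3 / 4)
  expect_equal(unname(b$contrast[1, ]), c(a, -a / 3, -a / 3, -a / 3))

  b2 <- pivot_basis(c("mvpa", "sleep", "sed", "lpa"))
  expect_equal(unname(b2$contrast[3, ]), c(0, 0, sqrt(1 / 2), -sqrt(1 / 2)))

  for (beh in behaviours()) {
    ctr <- pivot_basis(beh)$contrast
    expect_equal(ctr %*% t(ctr), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(ctr)), rep(0, 3), tolerance = 1e-12)
  }

  expect_error(pivot_basis(c("sleep", "sleep", "sed", "lpa")),
               class = "moveshift_schema_error")
  expect_error(pivot_basis("nap"), class = "moveshift_schema_error")
})

test_that("ilr coordinates follow the closed-form definition", {
  # equal parts sit at the origin of ilr space
  expect_equal(ilr_coords(c(sleep = 360, sed = 360, lpa = 360, mvpa = 360)),
               c(z1 = 0, z2 = 0, z3 = 0))

  x <- c(sleep = 0.5, sed = 0.25, lpa = 0.125, mvpa = 0.125)
  z <- ilr_coords(x)
  expect_equal(unname(z), unname(ilr_oracle(x)), tolerance = 1e-12)
  expect_equal(unname(z[3]), 0)  # lpa == mvpa

  # scale invariance: closure constant does not move the coordinates
  m <- random_comp_matrix(50, seed = 5)
  expect_equal(ilr_coords(m), ilr_coords(close_composition(m, kappa = 1)),
               tolerance = 1e-12)

  # every rotation agrees with the oracle
  for (beh in behaviours()) {
    b <- pivot_basis(beh)
    z_pkg <- ilr_coords(m[7, ], b)
    expect_equal(unname(z_pkg), unname(ilr_oracle(m[7, ], b$order)),
                 tolerance = 1e-12)
  }
})

test_that("ilr_inverse round-trips and maps the origin to the equal-part day", {
  expect_equal(ilr_inverse(c(0, 0, 0)),
               c(sleep = 360, sed = 360, lpa = 360, mvpa = 360))

  m <- random_comp_matrix(1000, seed = 9)
  back <- as.matrix(ilr_inverse(ilr_coords(m)))
  expect_lt(max(abs(back - m)), 1e-9)

  # recovers the closed children-like reference
  ref <- close_composition(c(sleep = 0.34, sed = 0.22, lpa = 0.39, mvpa = 0.02))
  expect_equal(ilr_inverse(ilr_coords(ref)), ref, tolerance = 1e-12)

  expect_error(ilr_inverse(c(0, Inf, 0)), class = "moveshift_numeric_error")
})

test_that("compositional mean is the ilr-space arithmetic mean", {
  m <- random_comp_matrix(40, seed = 21)
  cm <- comp_mean(m)
  oracle <- ilr_inverse(colMeans(ilr_coords(m)))
  expect_equal(unlist(cm), oracle, tolerance = 1e-9)

  # idempotence and proportionality
  one <- m[3, , drop = FALSE]
  expect_equal(unlist(comp_mean(one[c(1, 1, 1), ])), one[1, ], tolerance = 1e-12)
  two <- rbind(c(1, 1, 1, 1), c(4, 4, 4, 4))
  colnames(two) <- behaviours()
  expect_equal(unname(unlist(comp_mean(two))), rep(360, 4), tolerance = 1e-12)
})

test_that("variation matrix equals the pairwise enumeration oracle", {
  m <- random_comp_matrix(3, seed = 33)
  vm <- variation_matrix(m)
  for (i in 1:4) {
    for (j in 1:4) {
      expected <- if (i == j) 0 else var(log(m[, i] / m[, j]))
      expect_equal(vm[i, j], expected, tolerance = 1e-12)
    }
  }
  expect_equal(vm, t(vm))
  expect_true(all(vm >= 0))

  # exactly proportional parts give a zero entry
  prop <- cbind(sleep = c(100, 200, 50), sed = c(50, 100, 25),
                lpa = c(300, 100, 200), mvpa = c(10, 20, 30))
  vp <- variation_matrix(prop)
  expect_equal(vp["sleep", "sed"], 0)
  expect_gt(vp["sleep", "lpa"], 0)

  expect_error(variation_matrix(m[1, , drop = FALSE]),
               class = "moveshift_insufficient_data_error")
})
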
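# Shared fixtures and independent oracles for the test suite.

# Random strictly positive compositions (rows), via normalised gamma draws.
random_comp_matrix <- function(n, seed = NULL, kappa = 1440,
                               alpha = c(8, 6, 9, 2)) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), n, 4)
  m <- g / rowSums(g) * kappa
  colnames(m) <- behaviours()
  m
}

# Closed-form pivot ilr, written directly from the sequential-binary-partition
# definition (no matrix product): an oracle independent of ilr_coords().
ilr_oracle <- function(x, order = behaviours()) {
  x <- x[order]
  c(sqrt(3 / 4) * log(x[1] / prod(x[2:4])^(1 / 3)),
    sqrt(2 / 3) * log(x[2] / sqrt(x[3] * x[4])),
    sqrt(1 / 2) * log(x[3] / x[4]))
}

# Explicit normal-equations OLS: coefficients, SEs, R^2 from first principles.
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * XtX_inv))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), se = se, r2 = r2, sigma2 = sigma2, df = df)
}

# Cohort whose outcome is exactly linear in the canonical-order ilr
# coordinates (zero noise), for identifiability checks.
noiseless_cohort <- function(n = 60, beta = c(2, -3, 0.5), intercept = 50,
                             seed = 11) {
  m <- random_comp_matrix(n, seed = seed)
  z <- t(apply(m, 1, ilr_oracle))
  tibble::as_tibble(m) |>
    dplyr::mutate(fev1_pct_pred = intercept + drop(z %*% beta))
}

# Day-level fixture builder: one participant with the given wear hours and
# night validity flags; behaviour minutes are an arbitrary positive day.
make_days <- function(id, wear_hours, valid_nights) {
  nd <- length(wear_hours)
  tibble::tibble(
    participant_id = id, day_index = seq_len(nd),
    sleep = 480, sed = 330, lpa = 570, mvpa = 60,
    wear_min = wear_hours * 60,
    valid_night = rep_len(valid_nights, nd)
  )
}
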
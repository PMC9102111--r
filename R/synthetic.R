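#' Configuration for the synthetic cohort generator
#'
#' Defines a logistic-normal population on the 4-part behaviour simplex with
#' a linear outcome model in ilr space. Compositions are multivariate normal
#' in pivot ilr coordinates (canonical order sleep, SED, LPA, MVPA), so the
#' population compositional mean is exactly `ilr_inverse(ilr_mean)` and
#' every regression and reallocation truth is available in closed form.
#' The outcome is
#' `intercept + beta . z + covariate effects + N(0, noise_sd^2)`,
#' with sex coded female = 0 / male = 1 and genotype homozygous = 0 /
#' heterozygous = 1. The intercept is derived so the expected outcome at the
#' population means equals `outcome_mean`.
#'
#' @param n Number of participants.
#' @param comp_mean Target compositional mean as proportions (closed
#'   internally); determines `ilr_mean`.
#' @param ilr_cov 3 x 3 positive-definite covariance of the ilr coordinates.
#' @param beta True ilr coefficients (outcome points per unit coordinate).
#' @param covariate_effects Named vector of effects for `sex` (male vs
#'   female), `age` (per year) and `genotype` (heterozygous vs homozygous).
#' @param outcome_mean Expected outcome at the population means (percentage
#'   points).
#' @param noise_sd Residual SD of the outcome (percentage points).
#' @param age_range Uniform age range in years.
#' @param p_male,p_heterozygous Bernoulli probabilities for the binary
#'   covariates.
#' @param days_per_participant Days of accelerometer wear to simulate.
#' @param day_jitter_sd SD of the multiplicative log-normal day-to-day
#'   jitter around each participant's composition.
#' @param wear_mean_hours,wear_sd_hours Normal model for daily wear hours.
#' @param p_invalid_night Probability that a night fails sleep-window
#'   validation.
#' @param fail_fraction Fraction of participants constructed to fail the
#'   wear-time validity filter (their days are capped below the wear
#'   threshold).
#' @param seed Integer seed; mandatory, every draw flows from it.
#'
#' @return A `moveshift_config` list, including the derived `ilr_mean` and
#'   `intercept`.
#' @export
generator_config <- function(n,
                             comp_mean = c(sleep = 0.34, sed = 0.22,
                                           lpa = 0.39, mvpa = 0.02),
                             ilr_cov = diag(c(0.10, 0.12, 0.45)),
                             beta = c(16, -7, -5),
                             covariate_effects = c(sex = 6.9, age = -1.4,
                                                   genotype = 2.5),
                             outcome_mean = 86,
                             noise_sd = 18,
                             age_range = c(8, 17.9),
                             p_male = 0.5,
                             p_heterozygous = 0.45,
                             days_per_participant = 7,
                             day_jitter_sd = 0.15,
                             wear_mean_hours = 22, wear_sd_hours = 2,
                             p_invalid_night = 0.1,
                             fail_fraction = 0,
                             seed) {
  if (missing(seed)) abort("`seed` is required", class = "moveshift_config_error")
  if (n < 1) abort("`n` must be at least 1", class = "moveshift_config_error")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0", class = "moveshift_config_error")
  ilr_cov <- as.matrix(ilr_cov)
  if (!isTRUE(all.equal(ilr_cov, t(ilr_cov))) ||
      inherits(try(chol(ilr_cov), silent = TRUE), "try-error")) {
    abort("`ilr_cov` must be symmetric positive-definite",
          class = "moveshift_config_error")
  }
  comp_mean <- close_composition(comp_mean, kappa = 1)
  ilr_mean <- unname(ilr_coords(comp_mean))
  eff <- covariate_effects[c("sex", "age", "genotype")]
  intercept <- outcome_mean - sum(beta * ilr_mean) -
    eff[["sex"]] * p_male - eff[["age"]] * mean(age_range) -
    eff[["genotype"]] * p_heterozygous
  structure(list(
    n = as.integer(n), comp_mean = comp_mean, ilr_mean = ilr_mean,
    ilr_cov = ilr_cov, beta = beta, covariate_effects = eff,
    intercept = intercept, outcome_mean = outcome_mean, noise_sd = noise_sd,
    age_range = age_range, p_male = p_male, p_heterozygous = p_heterozygous,
    days_per_participant = as.integer(days_per_participant),
    day_jitter_sd = day_jitter_sd, wear_mean_hours = wear_mean_hours,
    wear_sd_hours = wear_sd_hours, p_invalid_night = p_invalid_night,
    fail_fraction = fail_fraction, seed = as.integer(seed)
  ), class = "moveshift_config")
}

#' Preset generator configurations
#'
#' Two ready-made populations: a paediatric-like cohort (n = 86, mean
#' composition 0.34/0.22/0.39/0.02 of the day in sleep/SED/LPA/MVPA, ages
#' 8-17.9, outcome centred at 86% predicted) and an adult-like cohort
#' (n = 43, mean composition 0.33/0.23/0.37/0.06, ages 18-35, outcome
#' centred at 63% predicted). Effect sizes and the 18-point residual SD are
#' chosen so the crude model explains roughly a tenth of the outcome
#' variance, typical of observational movement-behaviour cohorts.
#'
#' @param n,seed Overridable sample size and seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `moveshift_config`.
#' @export
children_like <- function(n = 86, seed = 2022, ...) {
  generator_config(n = n, seed = seed,
                   comp_mean = c(sleep = 0.34, sed = 0.22, lpa = 0.39,
                                 mvpa = 0.02),
                   outcome_mean = 86, age_range = c(8, 17.9),
                   p_heterozygous = 0.43, ...)
}

#' @rdname children_like
#' @export
adults_like <- function(n = 43, seed = 2022, ...) {
  generator_config(n = n, seed = seed,
                   comp_mean = c(sleep = 0.33, sed = 0.23, lpa = 0.37,
                                 mvpa = 0.06),
                   outcome_mean = 63, age_range = c(18, 35),
                   p_heterozygous = 0.53, ...)
}

# Multivariate normal draws via Cholesky (deterministic given the RNG state).
.rmvnorm <- function(n, mean, cov) {
  z <- matrix(rnorm(n * length(mean)), n, length(mean)) %*% chol(cov)
  sweep(z, 2, mean, "+")
}

#' Simulate a participant-level cohort with known ground truth
#'
#' Draws ilr coordinates from the configured multivariate normal, maps them
#' to closed 1440-min compositions, draws covariates, and generates the
#' outcome from the configured linear model plus Gaussian noise. Fully
#' deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `moveshift_sim`: `cohort` (analysis-ready
#'   tibble) and `truth` (per-participant true coordinates, expected
#'   outcome and realised noise), with the config attached as attribute.
#' @export
#' @examples
#' sim <- simulate_cohort(children_like(seed = 7))
#' head(sim$cohort)
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "moveshift_config"))
  set.seed(seed %||% config$seed)
  n <- config$n
  z <- .rmvnorm(n, config$ilr_mean, config$ilr_cov)
  comp <- ilr_inverse(z, kappa = 1440)
  sex <- ifelse(rbinom(n, 1, config$p_male) == 1, "male", "female")
  genotype <- ifelse(rbinom(n, 1, config$p_heterozygous) == 1,
                     "heterozygous", "homozygous")
  age <- runif(n, config$age_range[1], config$age_range[2])
  eff <- config$covariate_effects
  expected <- config$intercept + drop(z %*% config$beta) +
    eff[["sex"]] * (sex == "male") + eff[["age"]] * age +
    eff[["genotype"]] * (genotype == "heterozygous")
  noise <- rnorm(n, 0, config$noise_sd)
  id <- sprintf("P%04d", seq_len(n))
  cohort <- dplyr::bind_cols(
    tibble::tibble(participant_id = id), comp,
    tibble::tibble(fev1_pct_pred = expected + noise, age = age, sex = sex,
                   genotype = genotype,
                   age_group = ifelse(age >= 18, "adult", "child"))
  )
  truth <- tibble::tibble(participant_id = id, z1 = z[, 1], z2 = z[, 2],
                          z3 = z[, 3], expected = expected, noise = noise)
  structure(list(cohort = cohort, truth = truth), config = config,
            class = "moveshift_sim")
}

#' Simulate day-level accelerometer records
#'
#' Expands each participant's composition into `days_per_participant` daily
#' records with multiplicative log-normal jitter (re-closed to 1440 min),
#' wear time drawn from the configured normal model, and a validity flag per
#' night. The first `round(fail_fraction * n)` participants are constructed
#' to fail the wear-time filter: all their days are capped just below the
#' 16-h threshold. Conversely, non-failing participants are guaranteed at
#' least the qualifying days and nights, so the filter's inclusion set is
#' known by construction.
#'
#' @inheritParams simulate_cohort
#' @param min_wear_hours The wear threshold the construction targets
#'   (default 16 h).
#' @return A list: `days` (day-level tibble), `cohort` and `truth` as in
#'   [simulate_cohort()], and `constructed_failers` (participant ids).
#' @export
simulate_daily_records <- function(config, seed = NULL, min_wear_hours = 16) {
  sim <- simulate_cohort(config, seed = seed)  # seeds the RNG
  n <- config$n
  n_fail <- round(config$fail_fraction * n)
  failers <- sim$cohort$participant_id[seq_len(n_fail)]
  ndays <- config$days_per_participant
  comp <- .comp_matrix(sim$cohort)
  days <- purrr::map_dfr(seq_len(n), function(i) {
    jitter <- exp(matrix(rnorm(ndays * 4, 0, config$day_jitter_sd), ndays, 4))
    m <- sweep(jitter, 2, comp[i, ], "*")
    m <- m * (1440 / rowSums(m))
    colnames(m) <- behaviours()
    wear <- rnorm(ndays, config$wear_mean_hours * 60,
                  config$wear_sd_hours * 60)
    wear <- pmin(pmax(wear, 0), 1440)
    night <- rbinom(ndays, 1, 1 - config$p_invalid_night) == 1
    if (i <= n_fail) {
      wear <- pmin(wear, min_wear_hours * 60 - 6)  # all days 0.1 h short
    } else {
      k <- max(4, ceiling(ndays / 2))
      wear[seq_len(min(k, ndays))] <- pmax(wear[seq_len(min(k, ndays))],
                                           min_wear_hours * 60)
      night[seq_len(min(3, ndays))] <- TRUE
    }
    dplyr::bind_cols(
      tibble::tibble(participant_id = sim$cohort$participant_id[i],
                     day_index = seq_len(ndays)),
      tibble::as_tibble(m),
      tibble::tibble(wear_min = wear, valid_night = night)
    )
  })
  list(days = days, cohort = sim$cohort, truth = sim$truth,
       constructed_failers = failers)
}

#' True reallocation effect under a generator configuration
#'
#' The exact change in expected outcome when `delta` minutes move from one
#' behaviour to another starting from the population reference composition
#' (or a supplied one): `t(beta) %*% (z_new - z_ref)` with the configured
#' true coefficients.
#'
#' @inheritParams reallocate
#' @param config A [generator_config()].
#' @param reference Optional reference composition; defaults to the
#'   population compositional mean implied by the config.
#' @return The true outcome change (scalar, percentage points).
#' @export
true_delta <- function(config, from, to, delta, reference = NULL) {
  stopifnot(inherits(config, "moveshift_config"))
  ref <- if (is.null(reference)) {
    ilr_inverse(config$ilr_mean, kappa = 1440)
  } else {
    .ref_vector(reference)
  }
  new <- reallocate(.ref_vector(ref), from, to, delta)
  sum(config$beta * (ilr_coords(new) - ilr_coords(.ref_vector(ref))))
}
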
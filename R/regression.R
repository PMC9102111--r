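# Numeric coding used throughout: sex female = 0 / male = 1;
# genotype homozygous = 0 / heterozygous = 1; age in years, continuous.
.covariate_codes <- list(
  sex = c(female = 0, male = 1),
  genotype = c(homozygous = 0, heterozygous = 1)
)

.code_covariate <- function(x, name) {
  if (is.numeric(x)) return(x)
  codes <- .covariate_codes[[name]]
  if (is.null(codes)) {
    abort(sprintf("don't know how to code covariate '%s'", name),
          class = "moveshift_schema_error")
  }
  x <- as.character(x)
  unknown <- setdiff(unique(x[!is.na(x)]), names(codes))
  if (length(unknown) > 0) {
    abort(sprintf("covariate '%s' has unknown level(s): %s", name,
                  paste(unknown, collapse = ", ")),
          class = "moveshift_schema_error")
  }
  unname(codes[x])
}

#' Fit the compositional outcome model for one pivot rotation
#'
#' Ordinary least squares of the outcome on the three pivot ilr coordinates
#' of the behaviour composition, optionally adjusted for covariates. The
#' `retained` behaviour is placed first in the pivot order, so the z1
#' coefficient is the association of that behaviour relative to the
#' geometric mean of the remaining three, per unit increase in the log-ratio
#' coordinate. Coefficient p-values are two-sided t-tests on the residual
#' degrees of freedom; the whole-model p-value is the overall F-test.
#'
#' @param data Cohort data frame: the four behaviour columns (strictly
#'   positive minutes), the outcome column, and any covariates used.
#' @param retained Behaviour placed first in the pivot order (any of
#'   [behaviours()]); with the remaining parts kept in canonical relative
#'   order this defines the rotation.
#' @param covariates Character vector drawn from `c("sex", "age",
#'   "genotype")`, or `NULL` for the crude (unadjusted) model. Sex is coded
#'   female = 0 / male = 1 and genotype homozygous = 0 / heterozygous = 1.
#' @param outcome Name of the outcome column (default `"fev1_pct_pred"`).
#'
#' @return An object of class `ilr_fit`; see [tidy.ilr_fit()],
#'   [glance.ilr_fit()], [predict.ilr_fit()].
#' @export
#' @examples
#' sim <- simulate_cohort(children_like(seed = 1))
#' fit <- fit_ilr_model(sim$cohort, retained = "mvpa")
#' glance(fit)
fit_ilr_model <- function(data, retained = "sleep", covariates = NULL,
                          outcome = "fev1_pct_pred") {
  allowed <- c("sex", "age", "genotype")
  covariates <- covariates %||% character()
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")),
          class = "moveshift_config_error")
  }
  if (!outcome %in% names(data)) {
    abort(sprintf("outcome column '%s' not found", outcome),
          class = "moveshift_schema_error")
  }
  basis <- pivot_basis(retained)
  z <- ilr_coords(.comp_matrix(data), basis)
  df <- tibble::tibble(.outcome = data[[outcome]],
                       z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  for (cv in covariates) {
    if (!cv %in% names(data)) {
      abort(sprintf("covariate column '%s' not found", cv),
            class = "moveshift_schema_error")
    }
    df[[cv]] <- .code_covariate(data[[cv]], cv)
  }
  cc <- complete.cases(df)
  if (any(!cc)) {
    inform(sprintf("dropping %d row(s) with missing values (complete-case)",
                   sum(!cc)))
    df <- df[cc, ]
  }
  p <- 4L + length(covariates)  # intercept + 3 ilr + covariates
  if (nrow(df) <= p) {
    abort(sprintf("n = %d is too small for %d coefficients", nrow(df), p),
          class = "moveshift_insufficient_data_error")
  }
  rhs <- c("z1", "z2", "z3", covariates)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[rhs]))
  if (qr(X)$rank < ncol(X)) {
    abort(paste0("design matrix is rank deficient; check collinearity among: ",
                 paste(rhs, collapse = ", ")),
          class = "moveshift_collinearity_error")
  }
  fml <- stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = df)
  structure(list(
    lm = fit,
    basis = basis,
    retained = retained,
    covariates = covariates,
    outcome = outcome,
    n = nrow(df),
    covariate_means = if (length(covariates)) colMeans(df[covariates]) else NULL
  ), class = "ilr_fit")
}

# ilr-coefficient block and its covariance.
.coef_z <- function(fit) coef(fit$lm)[c("z1", "z2", "z3")]
.vcov_z <- function(fit) vcov(fit$lm)[c("z1", "z2", "z3"), c("z1", "z2", "z3")]

#' @export
print.ilr_fit <- function(x, ...) {
  s <- summary(x$lm)
  cat(sprintf("ilr outcome model (retained: %s%s), n = %d\n", x$retained,
              if (length(x$covariates)) paste0("; adjusted for ",
                                               paste(x$covariates, collapse = ", "))
              else "; crude", x$n))
  cat(sprintf("R^2 = %.4f, adj. R^2 = %.4f\n", s$r.squared, s$adj.r.squared))
  print(round(coef(s), 4))
  invisible(x)
}

#' Tidy the coefficients of an ilr outcome model
#'
#' @param x An [fit_ilr_model()] object.
#' @param conf.int,conf.level Add Wald t confidence intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `label` (what the coordinate contrasts),
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy ilr_fit
#' @export
tidy.ilr_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  s <- summary(x$lm)$coefficients
  ord <- x$basis$order
  labels <- c(
    "(Intercept)" = "(Intercept)",
    z1 = sprintf("%s vs rest", ord[1]),
    z2 = sprintf("%s vs (%s, %s)", ord[2], ord[3], ord[4]),
    z3 = sprintf("%s vs %s", ord[3], ord[4])
  )
  out <- tibble::tibble(
    term = rownames(s),
    label = ifelse(rownames(s) %in% names(labels),
                   labels[rownames(s)], rownames(s)),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
  if (isTRUE(conf.int)) {
    tcrit <- qt(1 - (1 - conf.level) / 2, x$lm$df.residual)
    out$conf.low <- out$estimate - tcrit * out$std.error
    out$conf.high <- out$estimate + tcrit * out$std.error
  }
  out
}

#' One-row model summary of an ilr outcome model
#'
#' @param x An [fit_ilr_model()] object.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared`, `sigma`, `statistic`
#'   (overall F), `p.value`, `df`, `df.residual`, `nobs`.
#' @method glance ilr_fit
#' @export
glance.ilr_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
    df = unname(f[2]), df.residual = x$lm$df.residual, nobs = x$n
  )
}

#' Predict the outcome for new behaviour compositions
#'
#' @param object An [fit_ilr_model()] object.
#' @param newdata Data frame with the four behaviour columns; adjusted models
#'   also need the covariate columns (raw or coded), or covariates are held
#'   at their sample means when absent.
#' @param ... Unused.
#' @return Numeric vector of predicted outcomes.
#' @export
predict.ilr_fit <- function(object, newdata, ...) {
  z <- ilr_coords(.comp_matrix(newdata, arg = "newdata"), object$basis)
  df <- tibble::tibble(z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  for (cv in object$covariates) {
    df[[cv]] <- if (cv %in% names(newdata)) {
      .code_covariate(newdata[[cv]], cv)
    } else {
      rep(object$covariate_means[[cv]], nrow(df))
    }
  }
  unname(predict(object$lm, newdata = df))
}

#' Fit all four pivot rotations
#'
#' Fits [fit_ilr_model()] once per behaviour placed first in the pivot
#' order. The four fits are the same model expressed in four orthonormal
#' bases: fitted values, R-squared, and every reallocation prediction agree
#' across rotations; only the coefficient parameterisation changes, giving
#' each behaviour an interpretable "vs the rest" coefficient.
#'
#' @inheritParams fit_ilr_model
#' @return Named list of `ilr_fit` objects (one per behaviour), class
#'   `ilr_rotations`.
#' @export
fit_rotations <- function(data, covariates = NULL, outcome = "fev1_pct_pred") {
  fits <- purrr::map(setNames(behaviours(), behaviours()),
                     ~ fit_ilr_model(data, retained = .x,
                                     covariates = covariates, outcome = outcome))
  structure(fits, class = "ilr_rotations")
}

#' @export
print.ilr_rotations <- function(x, ...) {
  cat("ilr outcome model in all four pivot rotations\n")
  print(glance(x[[1]]))
  invisible(x)
}

#' @method tidy ilr_rotations
#' @export
tidy.ilr_rotations <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy, .id = "retained", ...)
}

#' @method glance ilr_rotations
#' @export
glance.ilr_rotations <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance, .id = "retained")
}

#' Coefficient report across rotations
#'
#' One row per regressor per rotation (intercept omitted), starred at
#' `alpha`. With `labelling = "coordinates"` each row is labelled by what
#' its own pivot coordinate contrasts within that rotation (z1 = retained
#' behaviour vs rest, z2 and z3 the nested contrasts). With
#' `labelling = "first_pivot"` the report instead collects each behaviour's
#' z1 ("vs rest") coefficient from its own rotation — a compact
#' one-coefficient-per-behaviour summary.
#'
#' @param fits An `ilr_rotations` object (or a single `ilr_fit`).
#' @param labelling Row-labelling convention, see Details.
#' @param alpha Significance threshold for the star (inclusive).
#' @return A tibble with `retained`, `term`, `label`, `estimate`,
#'   `std.error`, `p.value`, `sig`.
#' @export
coefficient_table <- function(fits, labelling = c("coordinates", "first_pivot"),
                              alpha = 0.05) {
  labelling <- match.arg(labelling)
  if (inherits(fits, "ilr_fit")) {
    fits <- structure(setNames(list(fits), fits$retained), class = "ilr_rotations")
  }
  tab <- tidy(fits) |> dplyr::filter(.data$term != "(Intercept)")
  if (labelling == "first_pivot") {
    tab <- dplyr::filter(tab, .data$term == "z1")
  }
  dplyr::mutate(tab, sig = ifelse(.data$p.value <= alpha, "*", ""))
}
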
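# Ordered behaviour pairs in report order: Sleep to SED, Sleep to LPA, ...
.behaviour_pairs <- function() {
  bn <- behaviours()
  purrr::map_dfr(bn, function(f) {
    tibble::tibble(from = f, to = setdiff(bn, f))
  })
}

# Accept a reference as a one-row data frame or named vector; return a named
# numeric 4-vector in canonical order.
.ref_vector <- function(reference) {
  m <- .comp_matrix(reference, arg = "reference")
  if (nrow(m) != 1L) {
    abort("`reference` must be a single composition", class = "moveshift_schema_error")
  }
  m[1, ]
}

#' Reference composition of a cohort or stratum
#'
#' The compositional (geometric) mean of the cohort's behaviour
#' compositions, closed to a full day. Reallocation predictions are
#' expressed relative to this "average day".
#'
#' @param x Cohort data frame (or any table of compositions), or a single
#'   user-supplied composition (named vector / one-row data frame), which is
#'   simply closed.
#' @param kappa Closure constant in minutes.
#' @return A one-row tibble with the four behaviour columns summing to
#'   `kappa`; the provenance is recorded in attribute `"source"`.
#' @export
reference_composition <- function(x, kappa = 1440) {
  m <- .comp_matrix(x, arg = "x")
  if (nrow(m) == 0L) {
    abort("empty cohort: cannot form a reference composition",
          class = "moveshift_insufficient_data_error")
  }
  out <- comp_mean(m, kappa = kappa)
  attr(out, "source") <- if (nrow(m) == 1L) "user-supplied" else "cohort-mean"
  out
}

#' Move minutes between two behaviours of a reference day
#'
#' Subtracts `delta` minutes from one behaviour and adds them to another,
#' leaving the other parts and the 1440-min total untouched. The resulting
#' composition must remain strictly positive, so `delta` must be smaller
#' than the minutes available in `from`.
#'
#' @param reference A single composition (one-row data frame or named
#'   vector), normally from [reference_composition()].
#' @param from,to Behaviour names; must differ.
#' @param delta Minutes to move (>= 0).
#' @return The new composition, in the same shape as `reference`.
#' @export
#' @examples
#' ref <- c(sleep = 500, sed = 320, lpa = 590, mvpa = 30)
#' reallocate(ref, "sleep", "sed", 10)
reallocate <- function(reference, from, to, delta) {
  ref <- .ref_vector(reference)
  bn <- behaviours()
  if (!from %in% bn || !to %in% bn) {
    abort("`from` and `to` must be behaviour names", class = "moveshift_schema_error")
  }
  if (from == to) {
    abort("`from` and `to` must differ", class = "moveshift_schema_error")
  }
  .assert_scalar_number(delta, "delta", positive = FALSE)
  if (delta < 0) {
    abort("`delta` must be non-negative", class = "moveshift_schema_error")
  }
  if (delta >= ref[[from]]) {
    abort(sprintf(
      "infeasible reallocation: delta = %g min but only %g min of '%s' available (result must stay positive)",
      delta, ref[[from]], from), class = "moveshift_infeasible_error")
  }
  new <- ref
  new[[from]] <- new[[from]] - delta
  new[[to]] <- new[[to]] + delta
  .restore_comp(reference, matrix(new, 1, dimnames = list(NULL, bn)))
}

#' Predicted outcome change for one time reallocation
#'
#' Estimates the change in the model outcome when `delta` minutes are moved
#' from one behaviour to another, starting from the reference day. Because
#' the model is linear in the ilr coordinates, the intercept and covariate
#' terms cancel between the two predictions and the change is
#' `t(beta_z) %*% (z_new - z_ref)`; its confidence interval uses the
#' ilr-coefficient covariance block and t critical values on the residual
#' degrees of freedom. The estimate is identical (to numerical precision)
#' in all four pivot rotations.
#'
#' @param fit An [fit_ilr_model()] object.
#' @param reference The reference composition (see
#'   [reference_composition()]).
#' @param from,to,delta The reallocation: `delta` minutes from `from` to
#'   `to`.
#' @param ci_level Two-sided confidence level (default 0.95).
#' @return A one-row tibble: `from`, `to`, `delta`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `feasible`.
#' @export
predict_reallocation <- function(fit, reference, from, to, delta,
                                 ci_level = 0.95) {
  stopifnot(inherits(fit, "ilr_fit"))
  ref <- .ref_vector(reference)
  if (delta >= ref[[from]]) {
    return(tibble::tibble(from = from, to = to, delta = delta,
                          estimate = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          feasible = FALSE))
  }
  new <- reallocate(ref, from, to, delta)
  d <- ilr_coords(new, fit$basis) - ilr_coords(ref, fit$basis)
  b <- .coef_z(fit)
  est <- sum(b * d)
  se <- sqrt(drop(d %*% .vcov_z(fit) %*% d))
  tcrit <- qt(1 - (1 - ci_level) / 2, fit$lm$df.residual)
  tibble::tibble(from = from, to = to, delta = delta,
                 estimate = est, se = se,
                 ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                 feasible = TRUE)
}

#' Full reallocation grid
#'
#' [predict_reallocation()] for every ordered pair of distinct behaviours
#' (12 pairs, in report order: sleep to SED, sleep to LPA, ..., MVPA to LPA)
#' at each displacement in `deltas`. Cells whose displacement exceeds the
#' minutes available in the source behaviour are kept in the grid and
#' flagged `feasible = FALSE` rather than dropped.
#'
#' @inheritParams predict_reallocation
#' @param deltas Minutes to reallocate (default 10, 20, 30).
#' @return A tibble of 12 x `length(deltas)` rows, class `realloc_grid`,
#'   with the reference stored as attribute `"reference"`.
#' @export
reallocation_grid <- function(fit, reference, deltas = c(10, 20, 30),
                              ci_level = 0.95) {
  pairs <- .behaviour_pairs()
  grid <- tidyr::crossing(pairs, delta = sort(unique(deltas))) |>
    dplyr::arrange(factor(.data$from, levels = behaviours()),
                   factor(.data$to, levels = behaviours()), .data$delta)
  out <- purrr::pmap_dfr(grid, function(from, to, delta) {
    predict_reallocation(fit, reference, from, to, delta, ci_level)
  })
  attr(out, "reference") <- reference
  class(out) <- c("realloc_grid", class(out))
  out
}

#' Format a reallocation grid like a results table
#'
#' Wide layout with one row per ordered behaviour pair and one
#' `estimate (ci_low to ci_high)` column per displacement.
#'
#' @param grid A [reallocation_grid()] result.
#' @param digits Decimal places.
#' @return A tibble with a `reallocation` column and one column per delta.
#' @export
format_reallocation_grid <- function(grid, digits = 2) {
  lab <- .behaviour_labels
  grid |>
    dplyr::mutate(
      reallocation = paste(lab[.data$from], "to", lab[.data$to]),
      cell = ifelse(.data$feasible,
                    sprintf("%.*f (%.*f to %.*f)", digits, .data$estimate,
                            digits, .data$ci_low, digits, .data$ci_high),
                    "infeasible"),
      delta = paste0(.data$delta, " min")
    ) |>
    dplyr::select("reallocation", "delta", "cell") |>
    tidyr::pivot_wider(names_from = "delta", values_from = "cell")
}

#' Stratified reallocation grids
#'
#' Splits the cohort by the given stratifying columns, refits the model
#' within each stratum (crude by default), computes each stratum's own
#' reference composition (or reuses the whole-cohort reference), and
#' evaluates the reallocation grid per stratum. Strata below `min_n` are
#' skipped with a warning; strata below `warn_n` are analysed but flagged.
#'
#' @param data Cohort data frame.
#' @param strata Stratifying column names (default sex and genotype;
#'   add `"age_group"` for a mixed-age cohort).
#' @param deltas Minutes to reallocate (default 30).
#' @param covariates Covariates for the within-stratum model (default
#'   `NULL`, crude).
#' @param reference `"stratum"` (default) or `"overall"`.
#' @param min_n Minimum stratum size to analyse (default 8).
#' @param warn_n Stratum size below which a small-sample flag is set
#'   (default 15).
#' @inheritParams predict_reallocation
#' @param outcome Outcome column name.
#' @return A tibble: the stratifying columns, `n`, `small_sample`, then the
#'   grid columns. Skipped strata are listed in attribute `"skipped"`.
#' @export
stratified_grid <- function(data, strata = c("sex", "genotype"), deltas = 30,
                            covariates = NULL,
                            reference = c("stratum", "overall"),
                            min_n = 8, warn_n = 15, ci_level = 0.95,
                            outcome = "fev1_pct_pred") {
  reference <- match.arg(reference)
  missing_cols <- setdiff(strata, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("stratifying column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveshift_schema_error")
  }
  overall_ref <- reference_composition(data)
  groups <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::group_split()
  skipped <- list()
  out <- purrr::map_dfr(groups, function(g) {
    key <- g[1, strata, drop = FALSE]
    if (nrow(g) < min_n) {
      warn(sprintf("skipping stratum %s: n = %d < %d",
                   paste(unlist(key), collapse = "/"), nrow(g), min_n))
      skipped[[length(skipped) + 1]] <<- key
      return(NULL)
    }
    fit <- fit_ilr_model(g, retained = "sleep", covariates = covariates,
                         outcome = outcome)
    ref <- if (reference == "stratum") reference_composition(g) else overall_ref
    grid <- reallocation_grid(fit, ref, deltas = deltas, ci_level = ci_level)
    dplyr::bind_cols(
      key[rep(1, nrow(grid)), , drop = FALSE],
      tibble::tibble(n = nrow(g), small_sample = nrow(g) < warn_n),
      tibble::as_tibble(grid)
    )
  })
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else NULL
  out
}
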
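#' Wear-time validity filter for day-level accelerometer summaries
#'
#' Applies the inclusion rule used for free-living accelerometry: a day is
#' valid iff its wear time is at least `min_wear_hours` (inclusive), and a
#' participant is included iff they contribute at least `min_days` valid days
#' and at least `min_nights` valid nights. Night validity is taken from the
#' `valid_night` flag supplied with each day record (sleep-window detection
#' happens upstream of this package).
#'
#' @param days Day-level data frame with columns `participant_id`,
#'   `day_index`, the four behaviour columns, `wear_min` and `valid_night`.
#' @param min_days Minimum number of valid days (default 4).
#' @param min_nights Minimum number of valid nights (default 3).
#' @param min_wear_hours Minimum wear time for a valid day, in hours
#'   (default 16; the boundary is inclusive).
#'
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_days`, `n_valid_days`, `n_valid_nights`, `included`. The day-level
#'   table with a `valid_day` flag is attached as attribute `"days"`.
#' @export
filter_valid_participants <- function(days, min_days = 4, min_nights = 3,
                                      min_wear_hours = 16) {
  req <- c("participant_id", "wear_min", "valid_night")
  missing_cols <- setdiff(req, names(days))
  if (length(missing_cols) > 0) {
    abort(paste0("day records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveshift_schema_error")
  }
  if (any(!is.finite(days$wear_min)) || any(days$wear_min < 0) ||
      any(days$wear_min > 1440)) {
    bad <- which(!is.finite(days$wear_min) | days$wear_min < 0 | days$wear_min > 1440)[1]
    abort(sprintf("wear_min out of [0, 1440] at row %d", bad),
          class = "moveshift_schema_error")
  }
  days <- tibble::as_tibble(days)
  days$valid_day <- days$wear_min >= min_wear_hours * 60
  log <- days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      n_valid_days = sum(.data$valid_day),
      n_valid_nights = sum(as.logical(.data$valid_night)),
      .groups = "drop"
    ) |>
    dplyr::mutate(included = .data$n_valid_days >= min_days &
                    .data$n_valid_nights >= min_nights)
  attr(log, "days") <- days
  log
}

#' Average the valid days of each participant into one composition
#'
#' Takes the arithmetic per-behaviour mean of each participant's valid days
#' (in minute space) and closes the result to `kappa` minutes. Averaging is
#' arithmetic before closure, matching the plain reading of "an average of
#' all valid days"; compositional (geometric) averaging is available through
#' [comp_mean()] if preferred.
#'
#' @param days Day-level data frame restricted to the days to be averaged;
#'   a `participant_id` column groups days, otherwise all rows are treated
#'   as one participant.
#' @param kappa Closure constant in minutes.
#' @param zero_policy,replace_value Passed to [apply_zero_policy()] before
#'   closure.
#'
#' @return A tibble with `participant_id` (if present) and the four closed
#'   behaviour columns.
#' @export
average_valid_days <- function(days, kappa = 1440, zero_policy = "replace",
                               replace_value = 1) {
  if (nrow(days) < 1L) abort("no days to average", class = "moveshift_empty_input_error")
  days <- tibble::as_tibble(days)
  if (!"participant_id" %in% names(days)) days$participant_id <- "p1"
  out <- days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(behaviours()), mean),
                     .groups = "drop")
  out <- apply_zero_policy(out, policy = zero_policy, replace_value = replace_value)
  close_composition(out, kappa = kappa)
}

#' Zero-handling policy for behaviour minutes
#'
#' Screens behaviour values for zeros before they enter the composition.
#' `"reject"` raises an error naming the offending behaviour; `"replace"`
#' (the default elsewhere in the package) substitutes `replace_value`
#' minutes for each zero, leaving other parts untouched before closure, and
#' reports how many values were replaced.
#'
#' @param x Data frame with behaviour columns, or a numeric vector of 4
#'   parts; values must be non-negative.
#' @param policy `"replace"` or `"reject"`.
#' @param replace_value Minutes substituted for a zero (default 1).
#'
#' @return `x` with zeros handled, same shape as the input.
#' @export
#' @examples
#' apply_zero_policy(c(sleep = 480, sed = 300, lpa = 600, mvpa = 0))
apply_zero_policy <- function(x, policy = c("replace", "reject"),
                              replace_value = 1) {
  policy <- match.arg(policy)
  m <- .comp_matrix(x, allow_zero = TRUE)
  zero <- m == 0
  if (any(zero)) {
    if (policy == "reject") {
      j <- which(zero, arr.ind = TRUE)[1, ]
      abort(sprintf("zero minutes in behaviour '%s' (row %d) with policy 'reject'",
                    colnames(m)[j[["col"]]], j[["row"]]),
            class = "moveshift_zero_part_error")
    }
    .assert_scalar_number(replace_value, "replace_value")
    m[zero] <- replace_value
    inform(sprintf("replaced %d zero behaviour value(s) with %g min", sum(zero),
                   replace_value))
  }
  .restore_comp(x, m)
}

#' Assemble an analysis cohort from day-level records and participant metadata
#'
#' Runs the validity filter, averages each included participant's valid days
#' into a closed composition, applies the zero policy, and joins the
#' participant-level outcome and covariates. The derived `age_group` is
#' `"adult"` for age 18 and over, `"child"` otherwise.
#'
#' @param days Day-level records (see [filter_valid_participants()]).
#' @param meta Participant-level data frame with `participant_id`,
#'   `fev1_pct_pred`, `age`, `sex` (`"female"`/`"male"`) and `genotype`
#'   (`"homozygous"`/`"heterozygous"`).
#' @param min_days,min_nights,min_wear_hours Filter thresholds.
#' @param zero_policy,replace_value Zero handling for day averages.
#' @param kappa Closure constant in minutes.
#'
#' @return A cohort tibble (one row per included participant) with the four
#'   behaviour columns, outcome and covariates; the filter log is attached
#'   as attribute `"filter_log"`.
#' @export
build_cohort <- function(days, meta, min_days = 4, min_nights = 3,
                         min_wear_hours = 16, zero_policy = "replace",
                         replace_value = 1, kappa = 1440) {
  log <- filter_valid_participants(days, min_days, min_nights, min_wear_hours)
  dd <- attr(log, "days")
  included <- log$participant_id[log$included]
  if (length(included) == 0L) {
    abort("no participants meet the validity criteria",
          class = "moveshift_insufficient_data_error")
  }
  comps <- dd |>
    dplyr::filter(.data$valid_day, .data$participant_id %in% included) |>
    average_valid_days(kappa = kappa, zero_policy = zero_policy,
                       replace_value = replace_value)
  req <- c("participant_id", "fev1_pct_pred", "age", "sex", "genotype")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("participant metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveshift_schema_error")
  }
  cohort <- comps |>
    dplyr::inner_join(tibble::as_tibble(meta)[req], by = "participant_id") |>
    dplyr::mutate(age_group = ifelse(.data$age >= 18, "adult", "child"))
  attr(cohort, "filter_log") <- log
  cohort
}

# ---- I/O ---------------------------------------------------------------

# External CSV schema <-> internal column names.
.participant_schema <- c(
  participant_id = "participant_id", sleep = "sleep_min", sed = "sed_min",
  lpa = "lpa_min", mvpa = "mvpa_min", fev1_pct_pred = "fev1_pct_pred",
  age = "age_years", sex = "sex", genotype = "genotype"
)
.day_schema <- c(
  participant_id = "participant_id", day_index = "day_index",
  sleep = "sleep_min", sed = "sed_min", lpa = "lpa_min", mvpa = "mvpa_min",
  wear_min = "wear_min", valid_night = "valid_night"
)

.read_mapped <- function(path, schema, col_map = NULL) {
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("reading a YAML column map requires the 'yaml' package")
      }
      col_map <- unlist(yaml::read_yaml(col_map))
    }
    schema[names(col_map)] <- unname(col_map)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveshift_schema_error")
  }
  out <- raw[unname(schema)]
  names(out) <- names(schema)
  out
}

#' Read and write participant-level cohort files
#'
#' Cohort CSVs use the external schema `participant_id, sleep_min, sed_min,
#' lpa_min, mvpa_min, fev1_pct_pred, age_years, sex, genotype`; internal
#' tibbles use bare behaviour names and `age`. `col_map` renames external
#' columns (a named character vector `internal = "external"`, or the path of
#' a YAML file with the same structure). Write-then-read round-trips are
#' lossless.
#'
#' @param path CSV file path.
#' @param col_map Optional column renaming, see Details.
#' @return `read_cohort()`: a cohort tibble with derived `age_group`.
#' @export
read_cohort <- function(path, col_map = NULL) {
  out <- .read_mapped(path, .participant_schema, col_map)
  .comp_matrix(out)  # validates positivity
  dplyr::mutate(out, age_group = ifelse(.data$age >= 18, "adult", "child"))
}

#' @rdname read_cohort
#' @param cohort Cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  schema <- .participant_schema
  out <- cohort[names(schema)]
  names(out) <- unname(schema)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_daily <- function(path, col_map = NULL) {
  out <- .read_mapped(path, .day_schema, col_map)
  out$valid_night <- as.logical(out$valid_night)
  out
}

#' @rdname read_cohort
#' @param days Day-level tibble to write.
#' @export
write_daily <- function(days, path) {
  schema <- .day_schema
  out <- days[names(schema)]
  names(out) <- unname(schema)
  readr::write_csv(out, path)
  invisible(path)
}

# ---- Descriptives ------------------------------------------------------

#' Group descriptives with Welch t-tests
#'
#' Mean and SD of each continuous variable by group, with a Welch two-sample
#' t-test comparing the two groups and a significance flag at `alpha`.
#'
#' @param cohort Cohort tibble.
#' @param group_by Name of a two-level grouping column (e.g. `"age_group"`
#'   or `"sex"`).
#' @param variables Continuous variables to summarise; defaults to age,
#'   outcome and the four behaviours.
#' @param alpha Significance threshold (default 0.05, inclusive).
#'
#' @return A tibble with one row per variable: group means and SDs, the
#'   Welch t statistic, its p-value, and `significant`.
#' @export
cohort_descriptives <- function(cohort, group_by = "age_group",
                                variables = c("age", "fev1_pct_pred", behaviours()),
                                alpha = 0.05) {
  if (!group_by %in% names(cohort)) {
    abort(sprintf("grouping column '%s' not found", group_by),
          class = "moveshift_schema_error")
  }
  g <- as.character(cohort[[group_by]])
  levels_ <- sort(unique(g))
  if (length(levels_) != 2L) {
    abort(sprintf("'%s' must have exactly 2 levels, found %d", group_by,
                  length(levels_)),
          class = "moveshift_schema_error")
  }
  if (any(table(g) < 2L)) {
    abort("each group needs at least 2 members",
          class = "moveshift_insufficient_data_error")
  }
  purrr::map_dfr(variables, function(v) {
    x1 <- cohort[[v]][g == levels_[1]]
    x2 <- cohort[[v]][g == levels_[2]]
    if (sd(x1) == 0 && sd(x2) == 0 && mean(x1) == mean(x2)) {
      tt <- list(statistic = 0, p.value = 1)  # degenerate: identical constants
    } else {
      tt <- t.test(x1, x2)
    }
    tibble::tibble(
      variable = v,
      group1 = levels_[1], mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
      group2 = levels_[2], mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
      t = unname(tt$statistic), p.value = tt$p.value,
      significant = tt$p.value <= alpha
    )
  })
}

#' Lung-disease severity band from percent-predicted FEV1
#'
#' Labels disease severity as mild (> 70), moderate (40–69.99...) or severe
#' (< 40) percent predicted.
#'
#' @param fev1_pct_pred Numeric vector of percent-predicted FEV1.
#' @return Character vector of `"mild"`, `"moderate"`, `"severe"`.
#' @export
severity_band <- function(fev1_pct_pred) {
  dplyr::case_when(
    fev1_pct_pred > 70 ~ "mild",
    fev1_pct_pred >= 40 ~ "moderate",
    TRUE ~ "severe"
  )
}
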
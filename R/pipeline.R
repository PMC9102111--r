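#' Run the full compositional analysis and write a reproducible run directory
#'
#' Orchestrates the whole analysis for one cohort: optional day-level
#' filtering and averaging, descriptive statistics with group comparisons,
#' crude and adjusted ilr regressions in all four pivot rotations, the
#' reallocation grid from the crude model, stratified grids, optional
#' ternary panels, and a manifest of configuration plus SHA-256 checksums of
#' every table. All outputs are plain CSV/JSON and contain no timestamps,
#' so a rerun with identical inputs reproduces every file byte for byte.
#'
#' @param cohort Cohort tibble or path to a cohort CSV
#'   (see [read_cohort()]). Ignored when `days` and `meta` are supplied.
#' @param out_dir Output directory, created if needed.
#' @param days,meta Optional day-level records and participant metadata;
#'   when given, the cohort is built with [build_cohort()] and the filter
#'   log is written.
#' @param deltas Reallocation displacements in minutes.
#' @param covariates Covariates for the adjusted model.
#' @param strata Stratifying columns for the stratified grid (those present
#'   in the cohort are used; strata below the size threshold are skipped).
#' @param stratified_delta Displacement used in the stratified grid.
#' @param ci_level Confidence level for reallocation intervals.
#' @param zero_policy,replace_value Zero handling when building from days.
#' @param write_figures Also render the ternary panels as PNGs (figures are
#'   not covered by the byte-reproducibility guarantee of the tables).
#' @param label Cohort label recorded in the manifest.
#'
#' @return Invisibly, a named list of written file paths; key results
#'   (fits, grids, reference) are attached as attribute `"results"`.
#' @export
run_pipeline <- function(cohort = NULL, out_dir, days = NULL, meta = NULL,
                         deltas = c(10, 20, 30),
                         covariates = c("sex", "age", "genotype"),
                         strata = c("age_group", "sex", "genotype"),
                         stratified_delta = 30, ci_level = 0.95,
                         zero_policy = "replace", replace_value = 1,
                         write_figures = FALSE, label = "cohort") {
  # validate configuration before any compute
  bad <- setdiff(covariates, c("sex", "age", "genotype"))
  if (length(bad) > 0) {
    abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")),
          class = "moveshift_config_error")
  }
  if (any(deltas <= 0)) {
    abort("`deltas` must be positive", class = "moveshift_config_error")
  }
  deltas <- sort(deltas)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "moveshift_pipeline_error")
    })
  }

  filter_log <- NULL
  if (!is.null(days)) {
    cohort <- stage("filter", {
      co <- build_cohort(days, meta, zero_policy = zero_policy,
                         replace_value = replace_value)
      filter_log <- attr(co, "filter_log")
      paths$filter_log <- file.path(out_dir, "filter_log.csv")
      readr::write_csv(filter_log, paths$filter_log)
      co
    })
  } else if (is.character(cohort)) {
    cohort <- stage("load", read_cohort(cohort))
  }
  if (is.null(cohort)) {
    abort("supply `cohort`, or `days` with `meta`",
          class = "moveshift_config_error")
  }
  cohort <- tibble::as_tibble(cohort)

  # descriptives: compare age groups when both are present, else sexes
  desc_group <- if (length(unique(cohort$age_group)) == 2) "age_group" else "sex"
  stage("descriptives", {
    desc <- cohort_descriptives(cohort, group_by = desc_group)
    paths$descriptives <- file.path(out_dir, "descriptives.csv")
    readr::write_csv(desc, paths$descriptives)
  })

  stage("variation_matrix", {
    vm <- variation_matrix(cohort)
    vm_df <- tibble::as_tibble(vm, rownames = "behaviour")
    paths$variation_matrix <- file.path(out_dir, "variation_matrix.csv")
    readr::write_csv(vm_df, paths$variation_matrix)
  })

  fits_crude <- stage("fit_crude", fit_rotations(cohort))
  fits_adj <- stage("fit_adjusted", fit_rotations(cohort, covariates = covariates))
  stage("coefficient_tables", {
    paths$coefficients_crude <- file.path(out_dir, "coefficients_crude.csv")
    readr::write_csv(coefficient_table(fits_crude), paths$coefficients_crude)
    paths$coefficients_adjusted <- file.path(out_dir, "coefficients_adjusted.csv")
    readr::write_csv(coefficient_table(fits_adj), paths$coefficients_adjusted)
    paths$model_summaries <- file.path(out_dir, "model_summaries.csv")
    readr::write_csv(dplyr::bind_rows(crude = glance(fits_crude),
                                      adjusted = glance(fits_adj),
                                      .id = "model"),
                     paths$model_summaries)
  })

  ref <- stage("reference", reference_composition(cohort))
  grid <- stage("reallocation_grid", {
    g <- reallocation_grid(fits_crude$sleep, ref, deltas = deltas,
                           ci_level = ci_level)
    paths$reallocation_grid <- file.path(out_dir, "reallocation_grid.csv")
    readr::write_csv(tibble::as_tibble(g), paths$reallocation_grid)
    paths$reallocation_table <- file.path(out_dir, "reallocation_table.csv")
    readr::write_csv(format_reallocation_grid(g), paths$reallocation_table)
    g
  })

  strata_use <- intersect(strata, names(cohort))
  strata_use <- strata_use[purrr::map_int(strata_use,
                                          ~ length(unique(cohort[[.x]]))) > 1]
  strat <- NULL
  if (length(strata_use) > 0) {
    strat <- stage("stratified_grid", {
      s <- withCallingHandlers(
        stratified_grid(cohort, strata = strata_use,
                        deltas = stratified_delta, ci_level = ci_level),
        warning = function(w) invokeRestart("muffleWarning")
      )
      paths$stratified_grid <- file.path(out_dir, "stratified_grid.csv")
      readr::write_csv(tibble::as_tibble(s), paths$stratified_grid)
      s
    })
  }

  if (write_figures) {
    stage("figures", {
      paths$figures <- render_ternary_panels(fits_crude$sleep, ref,
                                              cohort = cohort,
                                              out_dir = file.path(out_dir, "figures"))
    })
  }

  stage("manifest", {
    tables <- purrr::keep(paths, is.character)
    tables <- purrr::keep(tables, ~ length(.x) == 1 && grepl("\\.csv$", .x))
    manifest <- list(
      package = "moveshift",
      version = as.character(utils::packageVersion("moveshift")),
      label = label,
      n = nrow(cohort),
      config = list(deltas = deltas, covariates = covariates,
                    strata = strata_use, stratified_delta = stratified_delta,
                    ci_level = ci_level, zero_policy = zero_policy),
      reference_composition = as.list(round(unlist(ref), 10)),
      checksums = purrr::map(tables, ~ digest::digest(file = .x, algo = "sha256"))
    )
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })

  results <- list(cohort = cohort, filter_log = filter_log,
                  fits_crude = fits_crude, fits_adjusted = fits_adj,
                  reference = ref, grid = grid, stratified = strat)
  invisible(structure(paths, results = results))
}
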
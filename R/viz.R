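# The four standard panel triples (varying behaviours; the remaining one is
# held at its reference value): A sed/sleep/mvpa, B sed/lpa/mvpa,
# C lpa/sleep/mvpa, D lpa/sleep/sed.
.standard_panels <- function() {
  list(A = c("sed", "sleep", "mvpa"), B = c("sed", "lpa", "mvpa"),
       C = c("lpa", "sleep", "mvpa"), D = c("lpa", "sleep", "sed"))
}

# Barycentric -> cartesian with corners axes[1] = (0,0), axes[2] = (1,0),
# axes[3] = (0.5, sqrt(3)/2).
.bary_xy <- function(a, b, c_) {
  list(x = b + 0.5 * c_, y = sqrt(3) / 2 * c_)
}

#' Predicted-outcome surface over a ternary sub-composition
#'
#' Evaluates the fitted model over a barycentric grid of three behaviours,
#' with the fourth behaviour held at its reference-composition value and the
#' varying triple scaled into the remaining minutes of the day, so every
#' grid point is a valid 1440-min composition. Grid points implying a
#' non-positive part (the triangle's edges and corners) are masked.
#' Predictions for adjusted models hold covariates at their sample means.
#'
#' @param fit An [fit_ilr_model()] object.
#' @param reference The reference composition.
#' @param axes Ordered triple of behaviour names spanning the triangle
#'   (corner order: bottom-left, bottom-right, top).
#' @param resolution Grid subdivisions per edge; the grid has
#'   `(resolution + 1) * (resolution + 2) / 2` points before masking.
#' @return A tibble of class `ternary_surface`: barycentric proportions
#'   `a`, `b`, `c`, minutes of each axis behaviour, cartesian `x`, `y`,
#'   `prediction` (NA when masked) and `masked`. Panel metadata (axes,
#'   fixed part and minutes, the prediction at the reference) is attached
#'   as attributes.
#' @export
ternary_surface <- function(fit, reference, axes = c("sed", "sleep", "mvpa"),
                            resolution = 64) {
  stopifnot(inherits(fit, "ilr_fit"))
  bn <- behaviours()
  if (length(axes) != 3L || anyDuplicated(axes) || !all(axes %in% bn)) {
    abort("`axes` must be three distinct behaviour names",
          class = "moveshift_config_error")
  }
  ref <- .ref_vector(reference)
  fixed <- setdiff(bn, axes)
  fixed_min <- ref[[fixed]]
  budget <- 1440 - fixed_min
  if (budget <= 0) {
    abort("fixed part uses the whole day; nothing left for the varying triple",
          class = "moveshift_config_error")
  }
  r <- as.integer(resolution)
  ij <- tidyr::crossing(i = 0:r, j = 0:r) |> dplyr::filter(.data$i + .data$j <= r)
  a <- ij$i / r
  b <- ij$j / r
  c_ <- (r - ij$i - ij$j) / r  # integer arithmetic keeps the boundary exact
  parts <- cbind(a, b, c_) * budget
  colnames(parts) <- axes
  masked <- apply(parts, 1, function(p) any(p <= 0))
  comp <- matrix(fixed_min, nrow(parts), 4,
                 dimnames = list(NULL, c(fixed, axes)))[, bn, drop = FALSE]
  comp[, axes] <- parts
  pred <- rep(NA_real_, nrow(comp))
  if (any(!masked)) {
    pred[!masked] <- predict(fit, comp[!masked, , drop = FALSE])
  }
  xy <- .bary_xy(a, b, c_)
  out <- dplyr::bind_cols(
    tibble::tibble(a = a, b = b, c = c_),
    tibble::as_tibble(parts),
    tibble::tibble(x = xy$x, y = xy$y, prediction = pred, masked = masked)
  )
  ref_pred <- predict(fit, matrix(ref, 1, dimnames = list(NULL, bn)))
  structure(out, axes = axes, fixed_part = fixed, fixed_min = fixed_min,
            resolution = r, reference_pred = ref_pred,
            class = c("ternary_surface", class(out)))
}

# Project cohort points into a panel's triangle: keep the three axis
# behaviours and renormalise the triple.
.project_points <- function(cohort, axes) {
  m <- .comp_matrix(cohort)[, axes, drop = FALSE]
  m <- m / rowSums(m)
  xy <- .bary_xy(m[, 1], m[, 2], m[, 3])
  tibble::tibble(x = xy$x, y = xy$y)
}

#' Plot a ternary prediction surface
#'
#' Heat-mapped triangle of model predictions with a diverging colour scale
#' centred at the prediction for the reference day, so colour reads as the
#' predicted outcome change relative to the cohort's average day. Cohort
#' points, projected onto the panel's triple, can be overlaid.
#'
#' @param object A [ternary_surface()].
#' @param cohort Optional cohort data frame to overlay as points.
#' @param point_alpha Overlay point transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ternary_surface
#' @export
autoplot.ternary_surface <- function(object, cohort = NULL, point_alpha = 0.5,
                                     ...) {
  axes <- attr(object, "axes")
  lab <- .behaviour_labels[axes]
  surf <- dplyr::filter(tibble::as_tibble(object), !.data$masked)
  frame <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  corners <- tibble::tibble(
    x = c(-0.04, 1.04, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
    label = unname(lab)
  )
  p <- ggplot2::ggplot(surf, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$prediction), size = 1.1) +
    ggplot2::scale_colour_gradient2(
      low = "#b2182b", mid = "#f7f7f7", high = "#2166ac",
      midpoint = attr(object, "reference_pred"),
      name = "Predicted\noutcome (%)"
    ) +
    ggplot2::geom_path(data = frame, linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_text(data = corners, ggplot2::aes(label = .data$label),
                       size = 3.2) +
    ggplot2::coord_fixed(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::labs(caption = sprintf("%s fixed at %.0f min",
                                    .behaviour_labels[attr(object, "fixed_part")],
                                    attr(object, "fixed_min")))
  if (!is.null(cohort)) {
    p <- p + ggplot2::geom_point(data = .project_points(cohort, axes),
                                 size = 0.7, alpha = point_alpha,
                                 colour = "grey20")
  }
  p
}

#' Compute the four standard ternary panels
#'
#' Panels A-D vary (SED, sleep, MVPA), (SED, LPA, MVPA), (LPA, sleep, MVPA)
#' and (LPA, sleep, SED) respectively, each with the remaining behaviour
#' fixed at its reference value.
#'
#' @inheritParams ternary_surface
#' @return Named list of four [ternary_surface()] objects.
#' @export
ternary_panels <- function(fit, reference, resolution = 64) {
  purrr::map(.standard_panels(),
             ~ ternary_surface(fit, reference, axes = .x,
                               resolution = resolution))
}

#' Render the standard panels to image files
#'
#' Writes one image per panel and, when the `patchwork` package is
#' available, a combined 2 x 2 figure.
#'
#' @inheritParams ternary_panels
#' @param cohort Optional cohort overlay.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` or `"svg"` (svg requires the `svglite` package).
#' @param width,height,dpi Device settings per panel.
#' @return Invisibly, the written file paths.
#' @export
render_ternary_panels <- function(fit, reference, cohort = NULL,
                                  out_dir = ".", format = "png",
                                  resolution = 64, width = 4.5, height = 4,
                                  dpi = 150) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- ternary_panels(fit, reference, resolution = resolution)
  paths <- character()
  plots <- purrr::imap(panels, function(s, nm) {
    autoplot(s, cohort = cohort) + ggplot2::ggtitle(paste("Panel", nm))
  })
  for (nm in names(plots)) {
    f <- file.path(out_dir, sprintf("ternary_panel_%s.%s", nm, format))
    ggplot2::ggsave(f, plots[[nm]], width = width, height = height, dpi = dpi)
    paths <- c(paths, f)
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    combined <- patchwork::wrap_plots(plots, ncol = 2)
    f <- file.path(out_dir, paste0("ternary_panels.", format))
    ggplot2::ggsave(f, combined, width = 2 * width, height = 2 * height,
                    dpi = dpi)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Plot a reallocation grid
#'
#' Dot-and-interval display of the predicted outcome change for every
#' ordered behaviour pair, faceted by displacement.
#'
#' @param object A [reallocation_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot realloc_grid
#' @export
autoplot.realloc_grid <- function(object, ...) {
  lab <- .behaviour_labels
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$feasible) |>
    dplyr::mutate(pair = factor(paste(lab[.data$from], "to", lab[.data$to]),
                                levels = rev(paste(lab[.behaviour_pairs()$from],
                                                   "to",
                                                   lab[.behaviour_pairs()$to]))),
                  delta = paste(.data$delta, "min"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25, colour = "grey40") +
    ggplot2::geom_point(size = 1.8, colour = "#2166ac") +
    ggplot2::facet_wrap(~ delta) +
    ggplot2::labs(x = "Predicted change in outcome (percentage points)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
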
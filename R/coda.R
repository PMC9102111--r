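#' Close a composition to a constant sum
#'
#' Rescales the four behaviour parts of each row so they sum to `kappa`
#' minutes (a full day by default). Closure is the fundamental operation of
#' Aitchison geometry: a composition carries only relative information, and
#' closing to 1440 min expresses it as a 24-hour day.
#'
#' @param x A data frame with columns `sleep`, `sed`, `lpa`, `mvpa` (minutes,
#'   strictly positive), or a matrix / named numeric vector of the four parts.
#' @param kappa Closure constant in minutes (default 1440, one day).
#'
#' @return The same shape as `x` with behaviour parts rescaled to sum to
#'   `kappa`; for data frames, all other columns are preserved and a tibble is
#'   returned.
#' @export
#' @examples
#' close_composition(c(sleep = 0.34, sed = 0.22, lpa = 0.39, mvpa = 0.02))
close_composition <- function(x, kappa = 1440) {
  .assert_scalar_number(kappa, "kappa")
  m <- .comp_matrix(x)
  s <- rowSums(m)
  # rows already summing to kappa (to rounding) pass through unchanged,
  # making closure exactly idempotent
  f <- ifelse(abs(s - kappa) <= 1e-12 * kappa, 1, kappa / s)
  m <- m * f
  .restore_comp(x, m)
}

#' Pivot (sequential-binary-partition) ilr basis
#'
#' Builds the orthonormal contrast matrix of pivot coordinates for the 4-part
#' behaviour composition. The first coordinate contrasts the first part of
#' `order` against the geometric mean of the remaining parts; each later
#' coordinate peels off the next part. "Rotations" of the basis place each
#' behaviour first in turn while keeping the others in canonical relative
#' order, so that every behaviour gets a coordinate interpretable as
#' "this behaviour relative to all others".
#'
#' @param order Either a full permutation of [behaviours()], or a single
#'   behaviour name to move to the front of the canonical order.
#'
#' @return An object of class `pivot_basis`: a list with `order` (character
#'   4-vector) and `contrast` (3 x 4 orthonormal matrix, rows summing to 0,
#'   columns named by `order`).
#' @export
#' @examples
#' pivot_basis("mvpa")
#' b <- pivot_basis()
#' b$contrast %*% t(b$contrast) # identity
pivot_basis <- function(order = behaviours()) {
  bn <- behaviours()
  if (is.character(order) && length(order) == 1L) {
    if (!order %in% bn) {
      abort(sprintf("unknown behaviour '%s'", order), class = "moveshift_schema_error")
    }
    order <- c(order, setdiff(bn, order))
  }
  if (length(order) != 4L || anyDuplicated(order) || !setequal(order, bn)) {
    abort("`order` must be a permutation of the four behaviour names",
          class = "moveshift_schema_error")
  }
  D <- 4L
  contrast <- matrix(0, D - 1L, D, dimnames = list(paste0("z", 1:(D - 1L)), order))
  for (i in seq_len(D - 1L)) {
    a <- sqrt((D - i) / (D - i + 1))
    contrast[i, i] <- a
    contrast[i, (i + 1L):D] <- -a / (D - i)
  }
  structure(list(order = order, contrast = contrast), class = "pivot_basis")
}

#' @export
print.pivot_basis <- function(x, ...) {
  cat("Pivot ilr basis, order:", paste(x$order, collapse = " > "), "\n")
  print(round(x$contrast, 4))
  invisible(x)
}

#' Forward ilr transform: compositions to pivot coordinates
#'
#' Maps strictly positive behaviour compositions to their three isometric
#' log-ratio coordinates, `z = V %*% log(x)` with `V` the pivot contrast
#' matrix. The result is invariant to the closure constant, so raw minutes
#' and closed proportions give identical coordinates.
#'
#' @param x A data frame with the four behaviour columns (plus any others),
#'   a matrix, or a named numeric vector.
#' @param basis A [pivot_basis()]; defaults to the canonical order.
#'
#' @return For data frames, a tibble: the input with columns `z1`, `z2`, `z3`
#'   appended. For matrices, an n x 3 matrix; for vectors, a named 3-vector.
#' @export
#' @examples
#' ilr_coords(c(sleep = 360, sed = 360, lpa = 360, mvpa = 360)) # all zero
ilr_coords <- function(x, basis = pivot_basis()) {
  stopifnot(inherits(basis, "pivot_basis"))
  m <- .comp_matrix(x)
  z <- log(m[, basis$order, drop = FALSE]) %*% t(basis$contrast)
  colnames(z) <- paste0("z", 1:3)
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
    out$z1 <- z[, 1]; out$z2 <- z[, 2]; out$z3 <- z[, 3]
    out
  } else if (is.matrix(x)) {
    z
  } else {
    z[1, ]
  }
}

#' Inverse ilr transform: pivot coordinates back to minutes
#'
#' Maps ilr coordinates back to a behaviour composition closed to `kappa`
#' minutes. Round-trips with [ilr_coords()] to within 1e-9 min.
#'
#' @param z A data frame with columns `z1`, `z2`, `z3`, a matrix with 3
#'   columns, or a numeric 3-vector.
#' @param basis The [pivot_basis()] the coordinates were computed in.
#' @param kappa Closure constant in minutes.
#'
#' @return A tibble with the four behaviour columns in canonical order (one
#'   row per input row), or a named vector for vector input.
#' @export
#' @examples
#' ilr_inverse(c(0, 0, 0)) # the equal-part day: 360 min each
ilr_inverse <- function(z, basis = pivot_basis(), kappa = 1440) {
  stopifnot(inherits(basis, "pivot_basis"))
  .assert_scalar_number(kappa, "kappa")
  zm <- if (is.data.frame(z)) {
    if (!all(paste0("z", 1:3) %in% names(z))) {
      abort("`z` must have columns z1, z2, z3", class = "moveshift_schema_error")
    }
    as.matrix(z[paste0("z", 1:3)])
  } else if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(zm) != 3L || anyNA(zm) || any(!is.finite(zm))) {
    abort("`z` must be finite ilr coordinates with 3 components",
          class = "moveshift_numeric_error")
  }
  m <- exp(zm %*% basis$contrast)      # columns in basis order
  m <- m * (kappa / rowSums(m))
  m <- m[, behaviours(), drop = FALSE] # back to canonical order
  if (is.data.frame(z) || is.matrix(z)) {
    tibble::as_tibble(m)
  } else {
    m[1, ]
  }
}

#' Compositional mean
#'
#' The closed vector of per-part geometric means across samples — the
#' composition whose ilr coordinates are the arithmetic mean of the sample
#' ilr coordinates. This is the natural centre of a compositional sample and
#' the usual "reference day" for reallocation analyses.
#'
#' @param x Data frame or matrix of behaviour compositions (one row per
#'   sample, all parts strictly positive).
#' @param kappa Closure constant in minutes.
#'
#' @return A one-row tibble with the four behaviour columns summing to
#'   `kappa`.
#' @export
comp_mean <- function(x, kappa = 1440) {
  m <- .comp_matrix(x)
  if (nrow(m) < 1L) abort("need at least one sample", class = "moveshift_empty_input_error")
  g <- exp(colMeans(log(m)))
  g <- g * (kappa / sum(g))
  tibble::as_tibble(as.list(g))
}

#' Pairwise log-ratio variation matrix
#'
#' Entry (i, j) is the sample variance (denominator n - 1) of
#' `log(part_i / part_j)` across samples. Entries near zero flag pairs of
#' behaviours that are nearly proportional across the cohort (highly
#' co-dependent); large entries flag pairs that vary freely relative to one
#' another. The matrix is symmetric with a zero diagonal and all entries
#' non-negative.
#'
#' @param x Data frame or matrix of behaviour compositions, at least 2 rows.
#'
#' @return A 4 x 4 numeric matrix with behaviour names as dimnames.
#' @export
variation_matrix <- function(x) {
  m <- .comp_matrix(x)
  if (nrow(m) < 2L) {
    abort("variation matrix needs at least 2 samples",
          class = "moveshift_insufficient_data_error")
  }
  lm_ <- log(m)
  bn <- behaviours()
  out <- matrix(0, 4, 4, dimnames = list(bn, bn))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      v <- var(lm_[, i] - lm_[, j])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}
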
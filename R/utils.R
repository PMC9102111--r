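# All numeric tolerances used across the package live here.
.ms_tol <- list(
  closure   = 1e-9,  # relative departure of a closed composition from kappa
  roundtrip = 1e-9,  # minutes, ilr_inverse(ilr_coords(x)) vs x
  orthonorm = 1e-12, # basis contrast orthonormality
  rotation  = 1e-8   # agreement of fits/predictions across pivot rotations
)

#' Canonical movement-behaviour names
#'
#' The four parts of the 24-hour day modelled by this package, in canonical
#' order: sleep, sedentary time (`sed`), light physical activity (`lpa`) and
#' moderate-to-vigorous physical activity (`mvpa`). This order fixes the
#' default pivot basis and the row order of reallocation grids.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' behaviours()
behaviours <- function() c("sleep", "sed", "lpa", "mvpa")

# Pretty labels used in tables and plots.
.behaviour_labels <- c(sleep = "Sleep", sed = "SED", lpa = "LPA", mvpa = "MVPA")

# Coerce the behaviour columns of `x` (data frame, matrix, or named numeric
# vector) to an n x 4 matrix in canonical column order. Validates presence,
# numeric type, finiteness and strict positivity (unless allow_zero).
.comp_matrix <- function(x, allow_zero = FALSE, arg = "x") {
  bn <- behaviours()
  if (is.data.frame(x)) {
    missing_cols <- setdiff(bn, names(x))
    if (length(missing_cols) > 0) {
      abort(sprintf("`%s` is missing behaviour column(s): %s", arg,
                    paste(missing_cols, collapse = ", ")),
            class = "moveshift_schema_error")
    }
    m <- as.matrix(x[bn])
  } else if (is.matrix(x)) {
    if (!is.null(colnames(x)) && all(bn %in% colnames(x))) {
      m <- x[, bn, drop = FALSE]
    } else if (ncol(x) == 4L) {
      m <- x
      colnames(m) <- bn
    } else {
      abort(sprintf("`%s` must have 4 behaviour columns", arg),
            class = "moveshift_schema_error")
    }
  } else if (is.numeric(x)) {
    if (!is.null(names(x)) && all(bn %in% names(x))) {
      m <- matrix(x[bn], nrow = 1, dimnames = list(NULL, bn))
    } else if (length(x) == 4L) {
      m <- matrix(x, nrow = 1, dimnames = list(NULL, bn))
    } else {
      abort(sprintf("`%s` must have 4 behaviour parts", arg),
            class = "moveshift_schema_error")
    }
  } else {
    abort(sprintf("`%s` must be a data frame, matrix or numeric vector", arg),
          class = "moveshift_schema_error")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    abort(sprintf("`%s` contains missing or non-finite behaviour values", arg),
          class = "moveshift_schema_error")
  }
  bad <- if (allow_zero) m < 0 else m <= 0
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    what <- if (allow_zero) "negative" else "non-positive"
    abort(sprintf("%s value in behaviour '%s' (row %d): compositions must be strictly positive",
                  what, colnames(m)[j[["col"]]], j[["row"]]),
          class = if (allow_zero) "moveshift_schema_error"
                  else "moveshift_zero_part_error")
  }
  m
}

# Return `data` with behaviour columns replaced by the rows of matrix `m`,
# preserving any other columns; non-data-frame inputs come back in kind.
.restore_comp <- function(x, m) {
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
    for (b in behaviours()) out[[b]] <- unname(m[, b])
    out
  } else if (is.matrix(x)) {
    m
  } else {
    m[1, ]
  }
}

.assert_scalar_number <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (positive && x <= 0)) {
    abort(sprintf("`%s` must be a single %s number", arg,
                  if (positive) "positive finite" else "finite"),
          class = "moveshift_schema_error")
  }
  invisible(x)
}
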
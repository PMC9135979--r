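#' Pixel grid of a 2D axial image
#'
#' Describes the sampling of a 2D scalar field: matrix extent plus physical
#' in-plane pixel spacing in millimetres. All physical coordinates in the
#' package are pixel-center anchored: pixel `(1, 1)` sits at physical
#' position `(0, 0)` mm and pixel `(i, j)` at
#' `((i - 1) * spacing_row_mm, (j - 1) * spacing_col_mm)`.
#'
#' @param n_rows,n_cols Matrix extent; both must be at least 3 so the
#'   nine-point Laplacian stencil has an interior.
#' @param spacing_row_mm,spacing_col_mm Physical pixel spacing (mm),
#'   strictly positive and finite.
#' @return An object of class `grid2d`.
#' @examples
#' grid2d(64, 64, 2.5, 2.5)
#' @export
grid2d <- function(n_rows, n_cols, spacing_row_mm = 1, spacing_col_mm = 1) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 3L || n_cols < 3L)
    stop("grid2d: n_rows and n_cols must be >= 3")
  if (!is.finite(spacing_row_mm) || !is.finite(spacing_col_mm) ||
      spacing_row_mm <= 0 || spacing_col_mm <= 0)
    stop("grid2d: spacings must be strictly positive and finite")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 spacing_row_mm = spacing_row_mm,
                 spacing_col_mm = spacing_col_mm),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d pixels, %.4g x %.4g mm spacing\n",
              x$n_rows, x$n_cols, x$spacing_row_mm, x$spacing_col_mm))
  invisible(x)
}

#' @export
format.grid2d <- function(x, ...) {
  sprintf("%dx%d@%gx%gmm", x$n_rows, x$n_cols,
          x$spacing_row_mm, x$spacing_col_mm)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$spacing_row_mm - b$spacing_row_mm) < tol &&
    abs(a$spacing_col_mm - b$spacing_col_mm) < tol
}

#' A 2D scalar field (SUV, dose, or dimensionless) on a grid
#'
#' The basic image container of the package: a numeric matrix plus its
#' [grid2d()] and a physical-quantity tag. SUV and dose fields must be
#' finite and nonnegative; dimensionless fields only finite.
#'
#' @param values Numeric matrix.
#' @param grid A [grid2d()] whose extent matches `dim(values)`.
#' @param quantity One of `"SUV"`, `"dose_Gy"`, `"dimensionless"`.
#' @return An object of class `scalar_field2d` with elements `values`,
#'   `grid`, `quantity`.
#' @examples
#' f <- scalar_field2d(matrix(1, 8, 8), grid2d(8, 8, 2.5, 2.5), "SUV")
#' @export
scalar_field2d <- function(values, grid, quantity = c("SUV", "dose_Gy",
                                                      "dimensionless")) {
  quantity <- match.arg(quantity)
  if (!is.matrix(values) || !is.numeric(values))
    stop("scalar_field2d: values must be a numeric matrix")
  if (!inherits(grid, "grid2d")) stop("scalar_field2d: grid must be a grid2d")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("scalar_field2d: values shape does not match grid")
  if (any(!is.finite(values)))
    stop("scalar_field2d: values must be finite everywhere")
  if (quantity %in% c("SUV", "dose_Gy") && any(values < 0))
    stop("scalar_field2d: ", quantity, " fields must be nonnegative")
  structure(list(values = values, grid = grid, quantity = quantity),
            class = "scalar_field2d")
}

#' @export
print.scalar_field2d <- function(x, ...) {
  cat(sprintf("<scalar_field2d> %s on %s, range [%.4g, %.4g]\n",
              x$quantity, format(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' A paired pre/dose/post case on a common grid
#'
#' Bundles the data triple the model is trained on: a pre-radiation SUV
#' image, the planned dose map, an optional ground-truth post-radiation SUV
#' image, and a body mask, all sharing one grid.
#'
#' @param pre `scalar_field2d` with quantity `"SUV"`.
#' @param dose `scalar_field2d` with quantity `"dose_Gy"`.
#' @param post Optional `scalar_field2d` with quantity `"SUV"`.
#' @param body_mask Logical matrix on the same grid with at least one
#'   `TRUE` pixel.
#' @param case_id Character identifier.
#' @param truth Optional list of ground-truth generator parameters (phantom
#'   cases carry the true alpha, beta and response operator here).
#' @return An object of class `paired_case`.
#' @export
paired_case <- function(pre, dose, post = NULL, body_mask, case_id,
                        truth = NULL) {
  stopifnot(inherits(pre, "scalar_field2d"), inherits(dose, "scalar_field2d"))
  if (pre$quantity != "SUV") stop("paired_case: pre must be an SUV field")
  if (dose$quantity != "dose_Gy") stop("paired_case: dose must be a dose field")
  if (!same_grid(pre$grid, dose$grid))
    stop("paired_case: pre and dose must share one grid")
  if (!is.null(post)) {
    stopifnot(inherits(post, "scalar_field2d"))
    if (!same_grid(pre$grid, post$grid))
      stop("paired_case: post must share the pre grid")
  }
  if (!is.logical(body_mask) || !identical(dim(body_mask), dim(pre$values)))
    stop("paired_case: body_mask must be a logical matrix on the same grid")
  if (!any(body_mask)) stop("paired_case: body_mask has no TRUE pixel")
  structure(list(pre = pre, dose = dose, post = post, body_mask = body_mask,
                 case_id = as.character(case_id), truth = truth),
            class = "paired_case")
}

#' @export
print.paired_case <- function(x, ...) {
  cat(sprintf("<paired_case> %s on %s, post: %s, body px: %d\n",
              x$case_id, format(x$pre$grid),
              if (is.null(x$post)) "absent" else "present",
              sum(x$body_mask)))
  invisible(x)
}
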
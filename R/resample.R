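#' Bilinearly resample a field onto a target grid
#'
#' Interpolates the field at the pixel centers of `target`, with both grids
#' anchored at the same physical origin (pixel-center convention: pixel
#' `(1, 1)` of either grid sits at `(0, 0)` mm). Query points outside the
#' source extent take the nearest-edge value (edge clamping), which avoids
#' spurious gradients at the field border. Values never leave the source
#' field's `[min, max]` range.
#'
#' @param field A [scalar_field2d()].
#' @param target A [grid2d()].
#' @return A `scalar_field2d` on `target` with the same quantity.
#' @export
resample_bilinear <- function(field, target) {
  stopifnot(inherits(field, "scalar_field2d"), inherits(target, "grid2d"))
  src <- field$grid
  if (same_grid(src, target)) {
    return(scalar_field2d(field$values, target, field$quantity))
  }
  # fractional source-pixel coordinates of target pixel centers (1-based)
  r <- 1 + (seq_len(target$n_rows) - 1) * target$spacing_row_mm / src$spacing_row_mm
  c_ <- 1 + (seq_len(target$n_cols) - 1) * target$spacing_col_mm / src$spacing_col_mm
  r <- pmin(pmax(r, 1), src$n_rows)
  c_ <- pmin(pmax(c_, 1), src$n_cols)
  r0 <- pmin(floor(r), src$n_rows - 1L); fr <- r - r0
  c0 <- pmin(floor(c_), src$n_cols - 1L); fc <- c_ - c0
  V <- field$values
  v00 <- V[cbind(rep(r0, target$n_cols), rep(c0, each = target$n_rows))]
  v10 <- V[cbind(rep(r0 + 1, target$n_cols), rep(c0, each = target$n_rows))]
  v01 <- V[cbind(rep(r0, target$n_cols), rep(c0 + 1, each = target$n_rows))]
  v11 <- V[cbind(rep(r0 + 1, target$n_cols), rep(c0 + 1, each = target$n_rows))]
  wr <- rep(fr, target$n_cols); wc <- rep(fc, each = target$n_rows)
  out <- (1 - wr) * (1 - wc) * v00 + wr * (1 - wc) * v10 +
    (1 - wr) * wc * v01 + wr * wc * v11
  out <- matrix(out, target$n_rows, target$n_cols)
  # guard tiny negative round-off on nonnegative quantities
  if (field$quantity != "dimensionless") out[out < 0] <- 0
  scalar_field2d(out, target, field$quantity)
}
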
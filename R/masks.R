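#' Select axial slices with sufficient FDG uptake
#'
#' Slice eligibility filter: keeps slices whose maximum SUV, outside an
#' optional exclusion mask, is strictly greater than the threshold
#' (default `1.5`). The exclusion mask generalizes brain-region exclusion:
#' excluded pixels do not count toward the maximum.
#'
#' @param slices List of `scalar_field2d`.
#' @param suv_max_threshold Nonnegative threshold; strict `>` comparison.
#' @param exclusion_mask Optional single logical matrix (applied to every
#'   slice) or list of per-slice logical matrices; `TRUE` marks excluded
#'   pixels.
#' @return Integer vector of eligible slice indices.
#' @export
select_eligible_slices <- function(slices, suv_max_threshold = 1.5,
                                   exclusion_mask = NULL) {
  if (suv_max_threshold < 0) stop("select_eligible_slices: threshold must be >= 0")
  masks <- NULL
  if (!is.null(exclusion_mask)) {
    masks <- if (is.list(exclusion_mask)) exclusion_mask
             else rep(list(exclusion_mask), length(slices))
    if (length(masks) != length(slices))
      stop("select_eligible_slices: one exclusion mask per slice required")
  }
  keep <- vapply(seq_along(slices), function(k) {
    v <- slices[[k]]$values
    if (!is.null(masks)) {
      m <- masks[[k]]
      if (!identical(dim(m), dim(v)))
        stop("select_eligible_slices: exclusion mask shape mismatch")
      v <- v[!m]
    }
    length(v) > 0 && max(v) > suv_max_threshold
  }, logical(1))
  which(keep)
}

#' Extract a body mask by thresholding and morphological cleanup
#'
#' Thresholds the field at `threshold`, keeps the largest 4-connected
#' component, and fills interior holes. Intended for delineating the body
#' region within which gamma analysis is restricted; the default SUV
#' threshold of 0.1 separates tissue (background SUV near 1) from air.
#'
#' @param field A `scalar_field2d`.
#' @param threshold Nonnegative threshold; pixels `>= threshold` are
#'   candidate foreground.
#' @param min_component_px Components smaller than this are never returned
#'   even if largest (guards degenerate speckle-only masks).
#' @return Logical matrix.
#' @export
extract_body_mask <- function(field, threshold = 0.1, min_component_px = 16) {
  if (threshold < 0) stop("extract_body_mask: threshold must be >= 0")
  fg <- field$values >= threshold
  if (!any(fg)) stop("extract_body_mask: no pixel above threshold")
  lab <- EBImage::bwlabel(fg + 0)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_component_px)
    stop("extract_body_mask: largest component below min_component_px")
  mask <- lab == best
  filled <- EBImage::fillHull(mask + 0)
  matrix(filled > 0, nrow(fg), ncol(fg))
}
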
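#' Read a 3D NIfTI volume as a list of axial slices
#'
#' Loads a 3D medical-image volume and splits it along the third dimension
#' into per-slice [scalar_field2d()] objects carrying the header's in-plane
#' pixel spacing. Slices are returned in decreasing third-index order, which
#' for superior-positive through-plane axes (the NIfTI default) corresponds
#' to superior-to-inferior reading order.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @param quantity Quantity tag applied to every slice.
#' @return List of `scalar_field2d`, one per axial slice.
#' @export
read_volume <- function(path, quantity = "SUV") {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: unreadable volume: ",
                                           conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))  # single-slice file
  if (length(dim(a)) != 3L)
    stop("read_volume: expected a 3D volume, got ", length(dim(a)), "D")
  pd <- RNifti::pixdim(img)
  g <- grid2d(dim(a)[1], dim(a)[2], pd[1], pd[2])
  lapply(rev(seq_len(dim(a)[3])), function(k)
    scalar_field2d(a[, , k], g, quantity))
}

#' Write a list of axial slices as one 3D NIfTI volume
#'
#' Inverse of [read_volume()]: slices given superior-to-inferior are stacked
#' in increasing third-index order so a write/read round trip returns the
#' slices in their original order with values preserved.
#'
#' @param slices List of `scalar_field2d` on a common grid.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param slice_thickness_mm Through-plane spacing recorded in the header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(slices, path, slice_thickness_mm = 2) {
  stopifnot(length(slices) >= 1)
  g <- slices[[1]]$grid
  for (s in slices)
    if (!same_grid(s$grid, g)) stop("write_volume: slices on different grids")
  a <- array(0, c(g$n_rows, g$n_cols, length(slices)))
  for (k in seq_along(slices)) a[, , length(slices) - k + 1L] <- slices[[k]]$values
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(g$spacing_row_mm, g$spacing_col_mm,
                           slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a single 2D field as a one-slice NIfTI
#' @param field A `scalar_field2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  write_volume(list(field), path)
}

#' Serialize a paired case to NIfTI fields plus a JSON sidecar
#'
#' Writes `<case_id>_pre.nii.gz`, `<case_id>_dose.nii.gz`, optionally
#' `<case_id>_post.nii.gz`, `<case_id>_mask.nii.gz`, and a
#' `<case_id>.json` sidecar holding grid, quantity, and any ground-truth
#' generator parameters.
#'
#' @param case A [paired_case()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, case$case_id)
  write_field(case$pre, paste0(base, "_pre.nii.gz"))
  write_field(case$dose, paste0(base, "_dose.nii.gz"))
  if (!is.null(case$post)) write_field(case$post, paste0(base, "_post.nii.gz"))
  g <- case$pre$grid
  mask_field <- scalar_field2d(case$body_mask + 0, g, "dimensionless")
  write_field(mask_field, paste0(base, "_mask.nii.gz"))
  side <- list(case_id = case$case_id,
               grid = unclass(g),
               has_post = !is.null(case$post),
               truth = case$truth)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(base, ".json"))
}

#' Read a paired case written by [write_case()]
#' @param dir Directory holding the files.
#' @param case_id Case identifier.
#' @return A [paired_case()].
#' @export
read_case <- function(dir, case_id) {
  base <- file.path(dir, case_id)
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  pre <- read_volume(paste0(base, "_pre.nii.gz"), "SUV")[[1]]
  dose <- read_volume(paste0(base, "_dose.nii.gz"), "dose_Gy")[[1]]
  post <- if (isTRUE(side$has_post))
    read_volume(paste0(base, "_post.nii.gz"), "SUV")[[1]] else NULL
  mask <- read_volume(paste0(base, "_mask.nii.gz"), "dimensionless")[[1]]
  paired_case(pre, dose, post, mask$values > 0.5, case_id,
              truth = side$truth)
}
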
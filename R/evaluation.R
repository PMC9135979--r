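#' Otsu threshold of a masked field
#'
#' Builds a 256-bin histogram of the in-mask values and picks the bin edge
#' maximizing between-class variance (Otsu's criterion, computed with bin
#' midpoints as class values). High-uptake pixels are the in-mask pixels
#' strictly above the threshold.
#'
#' @param field A `scalar_field2d`.
#' @param mask Logical matrix; defaults to all pixels.
#' @param n_bins Histogram bins (default 256).
#' @return List with `threshold` (numeric) and `high_uptake_mask`
#'   (logical matrix).
#' @export
otsu_threshold <- function(field, mask = NULL, n_bins = 256) {
  v <- field$values
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  if (!identical(dim(mask), dim(v)))
    stop("otsu_threshold: mask shape mismatch")
  x <- v[mask]
  if (length(unique(x)) < 2)
    stop("otsu_threshold: field is constant within the mask (degenerate histogram)")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  # between-class variance for split after bin t, vectorized over t
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu_t <- cm[n_bins]
  t_idx <- seq_len(n_bins - 1)
  w0 <- cw[t_idx]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0[valid] - cm[t_idx][valid])^2 /
    (w0[valid] * w1[valid])
  t_star <- which.max(sigma_b)
  threshold <- breaks[t_star + 1]
  list(threshold = threshold,
       high_uptake_mask = mask & (v > threshold))
}

#' Mean SUV within a mask
#' @param field A `scalar_field2d`.
#' @param mask Non-empty logical matrix.
#' @return Arithmetic mean of the in-mask values.
#' @export
suv_mean <- function(field, mask) {
  if (!identical(dim(mask), dim(field$values)))
    stop("suv_mean: mask shape mismatch")
  if (!any(mask)) stop("suv_mean: empty mask")
  mean(field$values[mask])
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`. When both masks are empty the overlap is
#' vacuously perfect: 1 is returned with a warning so cohort summaries
#' stay total.
#'
#' @param a,b Logical matrices of one shape.
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: shape mismatch")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("dice: both masks empty; returning 1 (vacuous agreement)")
    return(1.0)
  }
  2 * sum(a & b) / (na + nb)
}

#' Gamma-analysis criteria
#'
#' @param intensity_tol_percent Intensity tolerance as a percentage (of
#'   the reference body maximum under `global_max` normalization, or of
#'   the local reference value under `local`).
#' @param dta_mm Distance-to-agreement tolerance in mm.
#' @param normalization `"global_max"` (radiotherapy-QA convention,
#'   default) or `"local"`.
#' @param gamma_cap Gamma values above the cap are reported as the cap;
#'   the spatial search radius `gamma_cap * dta_mm` then decides
#'   pass/fail exactly.
#' @param upsample_factor Integer >= 1; bilinear sub-pixel sampling of the
#'   evaluated image.
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(intensity_tol_percent = 5, dta_mm = 5,
                           normalization = c("global_max", "local"),
                           gamma_cap = 2.0, upsample_factor = 1) {
  normalization <- match.arg(normalization)
  if (intensity_tol_percent <= 0 || dta_mm <= 0)
    stop("gamma_criteria: tolerances must be strictly positive")
  if (gamma_cap < 1) stop("gamma_criteria: gamma_cap must be >= 1")
  structure(list(intensity_tol_percent = intensity_tol_percent,
                 dta_mm = dta_mm, normalization = normalization,
                 gamma_cap = gamma_cap,
                 upsample_factor = as.integer(upsample_factor)),
            class = "gamma_criteria")
}

#' @export
format.gamma_criteria <- function(x, ...) {
  sprintf("%g%%/%gmm", x$intensity_tol_percent, x$dta_mm)
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %s, %s normalization, cap %g, upsample %d\n",
              format(x), x$normalization, x$gamma_cap, x$upsample_factor))
  invisible(x)
}

#' 2D gamma-index comparison of two images
#'
#' For every reference pixel inside the body mask, the gamma index is the
#' minimum over nearby evaluated positions of
#' `sqrt((dI / tol)^2 + (d / dta)^2)`, where `dI` is the intensity
#' difference, `tol` the absolute intensity tolerance, and `d` the physical
#' distance. The search covers evaluated grid positions (optionally
#' bilinearly up-sampled) within radius `gamma_cap * dta_mm`, which is
#' sufficient to compute gamma exactly up to the cap. A pixel passes when
#' gamma is strictly below 1; the passing rate is the percentage of body
#' pixels that pass.
#'
#' @param reference,evaluated `scalar_field2d` on one grid (reference =
#'   ground truth, evaluated = prediction).
#' @param body_mask Non-empty logical matrix.
#' @param criteria A [gamma_criteria()].
#' @return Object of class `gamma_result`: `gamma_map` (capped, `NA`
#'   outside the body), `passing_rate` (percent), `criteria`.
#' @export
gamma_index_2d <- function(reference, evaluated, body_mask,
                           criteria = gamma_criteria()) {
  if (!same_grid(reference$grid, evaluated$grid))
    stop("gamma_index_2d: images must share one grid")
  if (!any(body_mask)) stop("gamma_index_2d: empty body mask")
  g <- reference$grid
  R <- reference$values
  if (criteria$normalization == "global_max") {
    ref_max <- max(R[body_mask])
    if (ref_max <= 0)
      stop("gamma_index_2d: reference is all-zero inside the body mask")
    tol <- matrix(criteria$intensity_tol_percent / 100 * ref_max,
                  nrow(R), ncol(R))
  } else {
    tol <- criteria$intensity_tol_percent / 100 * R
  }
  f <- criteria$upsample_factor
  if (f > 1L) {
    fine <- grid2d((g$n_rows - 1) * f + 1, (g$n_cols - 1) * f + 1,
                   g$spacing_row_mm / f, g$spacing_col_mm / f)
    E <- resample_bilinear(evaluated, fine)$values
    sr <- fine$spacing_row_mm; sc <- fine$spacing_col_mm
    stride <- f
  } else {
    E <- evaluated$values
    sr <- g$spacing_row_mm; sc <- g$spacing_col_mm
    stride <- 1L
  }
  radius <- criteria$gamma_cap * criteria$dta_mm
  di_max <- floor(radius / sr); dj_max <- floor(radius / sc)
  H <- nrow(R); W <- ncol(R)
  He <- nrow(E); We <- ncol(E)
  best <- matrix(Inf, H, W)
  dta2 <- criteria$dta_mm^2
  for (di in -di_max:di_max) {
    d_r <- (di * sr)^2
    for (dj in -dj_max:dj_max) {
      d2 <- d_r + (dj * sc)^2
      if (d2 > radius^2) next
      # evaluated fine-grid index aligned with ref pixel (i, j): (i-1)*stride+1+di
      ri <- (seq_len(H) - 1L) * stride + 1L + di
      cj <- (seq_len(W) - 1L) * stride + 1L + dj
      vr <- which(ri >= 1L & ri <= He)
      vc <- which(cj >= 1L & cj <= We)
      if (!length(vr) || !length(vc)) next
      dI <- E[ri[vr], cj[vc], drop = FALSE] - R[vr, vc, drop = FALSE]
      tl <- tol[vr, vc, drop = FALSE]
      term <- ifelse(tl > 0, (dI / tl)^2,
                     ifelse(dI == 0, 0, Inf)) + d2 / dta2
      sub <- best[vr, vc, drop = FALSE]
      best[vr, vc] <- pmin(sub, term)
    }
  }
  gamma_map <- pmin(sqrt(best), criteria$gamma_cap)
  gamma_map[!body_mask] <- NA_real_
  passing <- 100 * sum(gamma_map[body_mask] < 1) / sum(body_mask)
  structure(list(gamma_map = gamma_map, passing_rate = passing,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: passing rate %.2f%%\n",
              format(x$criteria), x$passing_rate))
  invisible(x)
}

#' Evaluate a cohort of predictions against ground truth
#'
#' For each case: the Otsu high-uptake mask of the ground-truth post image
#' defines the region where mean SUV of truth and prediction are compared;
#' Dice is computed between the truth-derived and prediction-derived Otsu
#' masks; gamma analysis (truth as reference) is run for every criteria
#' set. Cohort summaries (median and mean passing rate per criteria set,
#' mean and sd of SUV means and Dice) are recomputable from the per-case
#' rows. Cases whose evaluation fails are recorded with a reason, not
#' silently dropped.
#'
#' @param cases List of [paired_case()] with post images.
#' @param predictions List of `scalar_field2d` predictions, parallel to
#'   `cases`.
#' @param criteria_sets List of [gamma_criteria()]; default
#'   5%/5mm, 5%/10mm, 10%/5mm, 10%/10mm.
#' @return Object of class `eval_report`: `rows` (per-case data frame),
#'   `summary` (list), `failed` (data frame of case_id / reason),
#'   `criteria_sets`.
#' @export
evaluate_cohort <- function(cases, predictions,
                            criteria_sets = default_criteria_sets()) {
  if (length(cases) != length(predictions))
    stop("evaluate_cohort: cases and predictions must be parallel lists")
  labels <- vapply(criteria_sets, format, "")
  rows <- list(); failed <- list()
  for (k in seq_along(cases)) {
    ck <- cases[[k]]
    res <- tryCatch({
      if (is.null(ck$post)) stop("missing post image")
      ot_truth <- otsu_threshold(ck$post, ck$body_mask)
      ot_pred <- otsu_threshold(predictions[[k]], ck$body_mask)
      row <- data.frame(
        case_id = ck$case_id,
        suv_mean_truth = suv_mean(ck$post, ot_truth$high_uptake_mask),
        suv_mean_pred = suv_mean(predictions[[k]], ot_truth$high_uptake_mask),
        dice = dice(ot_truth$high_uptake_mask, ot_pred$high_uptake_mask),
        stringsAsFactors = FALSE)
      for (ci in seq_along(criteria_sets)) {
        gr <- gamma_index_2d(ck$post, predictions[[k]], ck$body_mask,
                             criteria_sets[[ci]])
        row[[paste0("passing_", labels[ci])]] <- gr$passing_rate
      }
      row
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failed[[length(failed) + 1]] <-
        data.frame(case_id = ck$case_id, reason = res)
    else rows[[length(rows) + 1]] <- res
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character())
  failed <- if (length(failed)) do.call(rbind, failed) else
    data.frame(case_id = character(), reason = character())
  summ <- list(n_cases = nrow(rows),
               suv_mean_pred = c(mean = mean(rows$suv_mean_pred),
                                 sd = stats::sd(rows$suv_mean_pred)),
               suv_mean_truth = c(mean = mean(rows$suv_mean_truth),
                                  sd = stats::sd(rows$suv_mean_truth)),
               dice = c(mean = mean(rows$dice), sd = stats::sd(rows$dice)),
               passing_rate = lapply(stats::setNames(labels, labels),
                                     function(l) {
                                       p <- rows[[paste0("passing_", l)]]
                                       c(median = stats::median(p), mean = mean(p))
                                     }),
               otsu_convention = paste(
                 "SUV means: truth-derived Otsu mask applied to both images;",
                 "Dice: per-image Otsu masks"))
  structure(list(rows = rows, summary = summ, failed = failed,
                 criteria_sets = criteria_sets),
            class = "eval_report")
}

#' Default gamma criteria sets (5%/5, 5%/10, 10%/5, 10%/10)
#' @return List of four [gamma_criteria()].
#' @export
default_criteria_sets <- function() {
  list(gamma_criteria(5, 5), gamma_criteria(5, 10),
       gamma_criteria(10, 5), gamma_criteria(10, 10))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d cases (%d failed)\n",
              x$summary$n_cases, nrow(x$failed)))
  cat(sprintf("  SUV mean pred %.3f +/- %.3f, truth %.3f +/- %.3f, Dice %.3f +/- %.3f\n",
              x$summary$suv_mean_pred["mean"], x$summary$suv_mean_pred["sd"],
              x$summary$suv_mean_truth["mean"], x$summary$suv_mean_truth["sd"],
              x$summary$dice["mean"], x$summary$dice["sd"]))
  for (l in names(x$summary$passing_rate)) {
    p <- x$summary$passing_rate[[l]]
    cat(sprintf("  gamma %s: median %.2f%%, mean %.2f%%\n",
                l, p["median"], p["mean"]))
  }
  invisible(x)
}

#' Write an evaluation report to CSV + JSON
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the JSON path.
#' @export
write_eval_report <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rows,
                   file.path(dir, paste0(prefix, "_per_case.csv")),
                   row.names = FALSE)
  if (nrow(report$failed))
    utils::write.csv(report$failed,
                     file.path(dir, paste0(prefix, "_failed.csv")),
                     row.names = FALSE)
  jp <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(report$summary, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}
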
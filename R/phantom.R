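#' Specification of the synthetic phantom generator
#'
#' Describes the family of synthetic axial cases that stand in for patient
#' data: an elliptical body on a 64 x 64 grid at 2.5 mm spacing, background
#' SUV near 1 with mild noise, one to three Gaussian SUV hotspots with
#' clear edges (peak SUV 3-8, width 4-10 mm), and a smooth composite-
#' Gaussian dose field centred on the hotspots, rescaled to a 20 Gy maximum
#' and feathered to about 20% of the maximum far from the targets. The
#' post-radiation image is the model's own dynamics run forward with known
#' ground-truth parameters at a finer time discretization (`n_steps_sim`,
#' default 40 steps rather than the model's 4) so that learning from the
#' phantoms is not an inverse crime, plus additive truncated-Gaussian
#' noise inside the body.
#'
#' @param grid A [grid2d()] (default 64 x 64 at 2.5 mm).
#' @param n_hotspots Integer range `c(lo, hi)` of hotspot counts.
#' @param hotspot_peak_suv Range of peak SUV above background.
#' @param hotspot_sigma_mm Range of hotspot Gaussian widths (mm).
#' @param background_suv Body background SUV level.
#' @param background_noise_sd SD of pre-image noise (SUV units).
#' @param body_ellipse_axes_frac Ellipse semi-axes as fractions of the
#'   half-extent, `c(column_frac, row_frac)`.
#' @param dose_max_gy Prescribed dose maximum (Gy).
#' @param dose_sigma_mm Width of the dose Gaussians (mm).
#' @param dose_floor_frac Far-field dose as a fraction of the maximum.
#' @param true_alpha,true_beta Ground-truth coefficients of the simulated
#'   dynamics.
#' @param response List describing the ground-truth response operator:
#'   `list(type = "linear", gamma = )` or
#'   `list(type = "saturating", gamma = , psi_half = )`.
#' @param post_noise_sd SD of post-image noise (SUV units).
#' @param n_steps_sim Euler steps of the ground-truth simulation.
#' @param total_time Total integration time of the simulation.
#' @param seed Base seed; combined with each case seed for determinism.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid2d(64, 64, 2.5, 2.5),
                         n_hotspots = c(1, 3),
                         hotspot_peak_suv = c(3, 8),
                         hotspot_sigma_mm = c(4, 10),
                         background_suv = 1.0,
                         background_noise_sd = 0.05,
                         body_ellipse_axes_frac = c(0.8, 0.65),
                         dose_max_gy = 20,
                         dose_sigma_mm = 15,
                         dose_floor_frac = 0.2,
                         true_alpha = 0.05,
                         true_beta = -0.1,
                         response = list(type = "linear", gamma = 0.4),
                         post_noise_sd = 0.05,
                         n_steps_sim = 40,
                         total_time = 1,
                         seed = 0) {
  stopifnot(inherits(grid, "grid2d"))
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(n_hotspots) || !rng_ok(hotspot_peak_suv) ||
      !rng_ok(hotspot_sigma_mm))
    stop("phantom_spec: ranges must satisfy low <= high")
  if (background_noise_sd < 0 || post_noise_sd < 0)
    stop("phantom_spec: noise sds must be >= 0")
  if (dose_max_gy <= 0) stop("phantom_spec: dose_max_gy must be > 0")
  structure(list(grid = grid, n_hotspots = n_hotspots,
                 hotspot_peak_suv = hotspot_peak_suv,
                 hotspot_sigma_mm = hotspot_sigma_mm,
                 background_suv = background_suv,
                 background_noise_sd = background_noise_sd,
                 body_ellipse_axes_frac = body_ellipse_axes_frac,
                 dose_max_gy = dose_max_gy, dose_sigma_mm = dose_sigma_mm,
                 dose_floor_frac = dose_floor_frac,
                 true_alpha = true_alpha, true_beta = true_beta,
                 response = response, post_noise_sd = post_noise_sd,
                 n_steps_sim = as.integer(n_steps_sim),
                 total_time = total_time, seed = as.integer(seed)),
            class = "phantom_spec")
}

response_from_pars <- function(p) {
  switch(p$type,
         linear = linear_kill_response(p$gamma),
         saturating = saturating_kill_response(p$gamma, p$psi_half),
         zero = zero_response(),
         stop("unknown response type: ", p$type))
}

# centred ellipse body mask on the grid
ellipse_mask <- function(grid, axes_frac) {
  rr <- seq_len(grid$n_rows); cc <- seq_len(grid$n_cols)
  cy <- (grid$n_rows + 1) / 2; cx <- (grid$n_cols + 1) / 2
  ay <- axes_frac[2] * (grid$n_rows - 1) / 2
  ax <- axes_frac[1] * (grid$n_cols - 1) / 2
  outer(rr, cc, function(i, j) ((i - cy) / ay)^2 + ((j - cx) / ax)^2 <= 1)
}

#' Generate one synthetic paired case
#'
#' Deterministic given `(spec$seed, case_seed)`. Hotspot centres are
#' rejection-sampled inside the body ellipse (error after 100 tries). The
#' returned case carries the ground-truth parameters in `$truth`.
#'
#' @param spec A [phantom_spec()].
#' @param case_seed Integer distinguishing cases under one spec.
#' @return A [paired_case()] with `pre`, `dose`, `post`, `body_mask`,
#'   and ground truth attached.
#' @export
generate_case <- function(spec, case_seed = 1) {
  set.seed((spec$seed * 131071 + case_seed * 7919) %% 2147483647)
  g <- spec$grid
  body <- ellipse_mask(g, spec$body_ellipse_axes_frac)
  rows_mm <- (seq_len(g$n_rows) - 1) * g$spacing_row_mm
  cols_mm <- (seq_len(g$n_cols) - 1) * g$spacing_col_mm
  cy <- (g$n_rows + 1) / 2; cx <- (g$n_cols + 1) / 2
  ay <- spec$body_ellipse_axes_frac[2] * (g$n_rows - 1) / 2
  ax <- spec$body_ellipse_axes_frac[1] * (g$n_cols - 1) / 2

  nh <- if (spec$n_hotspots[1] == spec$n_hotspots[2]) spec$n_hotspots[1]
        else sample(spec$n_hotspots[1]:spec$n_hotspots[2], 1)
  centers <- matrix(0, nh, 2)  # (row, col) in pixels
  for (k in seq_len(nh)) {
    ok <- FALSE
    for (try in 1:100) {
      ri <- stats::runif(1, 1, g$n_rows); ci <- stats::runif(1, 1, g$n_cols)
      if (((ri - cy) / ay)^2 + ((ci - cx) / ax)^2 <= 0.8^2) {
        centers[k, ] <- c(ri, ci); ok <- TRUE; break
      }
    }
    if (!ok) stop("generate_case: could not place hotspot inside the body")
  }
  peaks <- stats::runif(nh, spec$hotspot_peak_suv[1], spec$hotspot_peak_suv[2])
  sigmas <- stats::runif(nh, spec$hotspot_sigma_mm[1], spec$hotspot_sigma_mm[2])

  gaussian2d <- function(center_px, sigma_mm) {
    dy <- rows_mm - (center_px[1] - 1) * g$spacing_row_mm
    dx <- cols_mm - (center_px[2] - 1) * g$spacing_col_mm
    outer(dy^2, dx^2, "+") |> (\(d2) exp(-d2 / (2 * sigma_mm^2)))()
  }

  pre_clean <- matrix(spec$background_suv, g$n_rows, g$n_cols)
  for (k in seq_len(nh))
    pre_clean <- pre_clean + peaks[k] * gaussian2d(centers[k, ], sigmas[k])
  pre_clean[!body] <- 0

  dose_raw <- matrix(0, g$n_rows, g$n_cols)
  for (k in seq_len(nh))
    dose_raw <- dose_raw + gaussian2d(centers[k, ], spec$dose_sigma_mm)
  dose_raw <- dose_raw / max(dose_raw)
  dose <- spec$dose_max_gy *
    (spec$dose_floor_frac + (1 - spec$dose_floor_frac) * dose_raw)

  pre_noisy <- pre_clean +
    ifelse(body, stats::rnorm(length(pre_clean), 0, spec$background_noise_sd), 0)
  pre_noisy <- pmax(pre_noisy, 0)

  params <- rd_params(alpha = spec$true_alpha, beta = spec$true_beta,
                      n_steps = spec$n_steps_sim,
                      total_time = spec$total_time)
  F_op <- response_from_pars(spec$response)
  # The response couples to dose expressed relative to the prescribed
  # maximum (psi = (D / dose_max) * U), so gamma is a per-unit-time rate at
  # full prescription dose; in absolute Gy a gamma of 0.4 would wipe out
  # the signal (exp(-8) survival at 20 Gy), which no intra-treatment PET
  # study shows.
  traj <- simulate_forward(
    scalar_field2d(pre_clean, g, "SUV"),
    scalar_field2d(dose / spec$dose_max_gy, g, "dimensionless"),
    params, F_op, clip_negative = TRUE)
  post <- traj$frames[[length(traj$frames)]]$values
  post[!body] <- 0
  post <- post +
    ifelse(body, stats::rnorm(length(post), 0, spec$post_noise_sd), 0)
  post <- pmax(post, 0)

  paired_case(
    pre = scalar_field2d(pre_noisy, g, "SUV"),
    dose = scalar_field2d(dose, g, "dose_Gy"),
    post = scalar_field2d(post, g, "SUV"),
    body_mask = body,
    case_id = sprintf("phantom_%05d", case_seed),
    truth = list(alpha = spec$true_alpha, beta = spec$true_beta,
                 response = spec$response,
                 n_steps_sim = spec$n_steps_sim,
                 hotspot_centers_px = centers,
                 hotspot_peaks = peaks, hotspot_sigmas_mm = sigmas,
                 pre_clean = pre_clean))
}

#' Generate a split phantom dataset
#'
#' Generates `n_cases` cases (case seeds `1:n_cases`) and partitions them
#' into disjoint train/validation/test sets by rounded fractions
#' (default 60%/20%/20%); membership is a seeded permutation, so it is
#' deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param n_cases Number of cases (at least 5).
#' @param split Fractions `c(train, val, test)` summing to 1.
#' @return List with elements `train`, `val`, `test` (lists of
#'   [paired_case()]) and `assignment` (data frame of case_id / split).
#' @export
generate_dataset <- function(spec, n_cases, split = c(0.6, 0.2, 0.2)) {
  if (abs(sum(split) - 1) > 1e-9)
    stop("generate_dataset: split fractions must sum to 1")
  if (n_cases < 5) stop("generate_dataset: n_cases must be >= 5")
  n_train <- round(split[1] * n_cases)
  n_val <- round(split[2] * n_cases)
  n_test <- n_cases - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("generate_dataset: every split must be non-empty")
  cases <- lapply(seq_len(n_cases), function(k) generate_case(spec, k))
  set.seed(spec$seed)
  perm <- sample.int(n_cases)
  idx_train <- perm[seq_len(n_train)]
  idx_val <- perm[n_train + seq_len(n_val)]
  idx_test <- perm[n_train + n_val + seq_len(n_test)]
  assignment <- data.frame(
    case_id = vapply(cases, function(c) c$case_id, ""),
    split = "train", stringsAsFactors = FALSE)
  assignment$split[idx_val] <- "val"
  assignment$split[idx_test] <- "test"
  list(train = cases[idx_train], val = cases[idx_val],
       test = cases[idx_test], assignment = assignment)
}
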
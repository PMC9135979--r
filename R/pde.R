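#' Reaction-diffusion parameters for the discretized model
#'
#' Governs the forward-Euler discretization of
#' `U_t = alpha * Laplacian(U) + beta * U + F(D * U)`:
#' diffusion coefficient `alpha` (pixel^2 per unit time, applied on the
#' pixel lattice), proliferation rate `beta` (per unit time), the number of
#' Euler steps `n_steps` (Nt) and the total integration time `total_time`
#' (T), with step size `h = T / Nt`. Defaults follow the model
#' configuration used throughout the package: `T = 1`, `Nt = 4`, so
#' `h = 0.25`.
#'
#' The explicit scheme with the nine-point stencil has nonnegative update
#' weights only when `h * alpha <= 1/3`; violating this emits a stability
#' warning but is not an error (some analyses intentionally probe the
#' unstable regime).
#'
#' @param alpha Diffusion coefficient, `>= 0` (zero allowed for degenerate
#'   dynamics).
#' @param beta Proliferation rate (may be negative: net decay).
#' @param n_steps Positive integer Nt.
#' @param total_time Positive total time T.
#' @return Object of class `rd_params` with derived element `h`.
#' @examples
#' rd_params(alpha = 0.05, beta = -0.1)
#' @export
rd_params <- function(alpha = 0.01, beta = 0, n_steps = 4, total_time = 1) {
  if (!is.finite(alpha) || alpha < 0) stop("rd_params: alpha must be >= 0")
  if (!is.finite(beta)) stop("rd_params: beta must be finite")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("rd_params: n_steps must be a positive integer")
  if (!is.finite(total_time) || total_time <= 0)
    stop("rd_params: total_time must be positive")
  h <- total_time / n_steps
  if (h * alpha > 1 / 3)
    warning(sprintf(paste0("rd_params: h * alpha = %.4g > 1/3; the explicit ",
                           "scheme has negative update weights (potentially ",
                           "unstable)"), h * alpha))
  structure(list(alpha = alpha, beta = beta, n_steps = n_steps,
                 total_time = total_time, h = h), class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat(sprintf("<rd_params> alpha=%.4g beta=%.4g Nt=%d T=%g (h=%g)\n",
              x$alpha, x$beta, x$n_steps, x$total_time, x$h))
  invisible(x)
}

# The nine-point Laplacian stencil. Coefficients sum to zero; the operator
# annihilates affine fields and is symmetric under rotation/transposition.
laplacian_stencil <- function() {
  matrix(c(1 / 4, 1 / 2, 1 / 4,
           1 / 2, -3,    1 / 2,
           1 / 4, 1 / 2, 1 / 4), 3, 3, byrow = TRUE)
}

pad_matrix <- function(U, boundary) {
  n <- nrow(U); m <- ncol(U)
  P <- matrix(0, n + 2, m + 2)
  P[2:(n + 1), 2:(m + 1)] <- U
  if (boundary == "replicate") {
    P[1, 2:(m + 1)] <- U[1, ]; P[n + 2, 2:(m + 1)] <- U[n, ]
    P[2:(n + 1), 1] <- U[, 1]; P[2:(n + 1), m + 2] <- U[, m]
    P[1, 1] <- U[1, 1]; P[1, m + 2] <- U[1, m]
    P[n + 2, 1] <- U[n, 1]; P[n + 2, m + 2] <- U[n, m]
  } else if (boundary == "periodic") {
    P[1, 2:(m + 1)] <- U[n, ]; P[n + 2, 2:(m + 1)] <- U[1, ]
    P[2:(n + 1), 1] <- U[, m]; P[2:(n + 1), m + 2] <- U[, 1]
    P[1, 1] <- U[n, m]; P[1, m + 2] <- U[n, 1]
    P[n + 2, 1] <- U[1, m]; P[n + 2, m + 2] <- U[1, 1]
  } # zero: already zero
  P
}

#' Nine-point discrete Laplacian
#'
#' Cross-correlation of `U` with the stencil
#' `[[1/4, 1/2, 1/4], [1/2, -3, 1/2], [1/4, 1/2, 1/4]]`, the refined
#' nine-point approximation of the 2D Laplacian on the pixel lattice.
#' Border pixels use the chosen boundary rule: `replicate` (edge values
#' extended, approximating zero flux; the default), `periodic` (torus), or
#' `zero` (zero padding).
#'
#' @param U Numeric matrix, at least 3 x 3.
#' @param boundary One of `"replicate"`, `"periodic"`, `"zero"`.
#' @return Matrix of the same shape.
#' @export
discrete_laplacian <- function(U, boundary = c("replicate", "periodic",
                                               "zero")) {
  boundary <- match.arg(boundary)
  if (!is.matrix(U) || nrow(U) < 3 || ncol(U) < 3)
    stop("discrete_laplacian: U must be a matrix of at least 3 x 3")
  if (any(!is.finite(U))) stop("discrete_laplacian: U must be finite")
  n <- nrow(U); m <- ncol(U)
  P <- pad_matrix(U, boundary)
  i <- 2:(n + 1); j <- 2:(m + 1)
  0.25 * (P[i - 1, j - 1] + P[i - 1, j + 1] + P[i + 1, j - 1] + P[i + 1, j + 1]) +
    0.5 * (P[i - 1, j] + P[i + 1, j] + P[i, j - 1] + P[i, j + 1]) -
    3 * U
}

# Adjoint of discrete_laplacian under the given boundary rule, needed for
# backpropagation through the unrolled solver. For periodic and zero
# boundaries the operator is self-adjoint; replicate padding adds a fold of
# the padded border back onto the edge pixels.
laplacian_adjoint <- function(G, boundary = "replicate") {
  n <- nrow(G); m <- ncol(G)
  if (boundary %in% c("periodic", "zero"))
    return(discrete_laplacian(G, boundary))
  # full correlation of G with the (symmetric) stencil onto the padded grid
  s <- laplacian_stencil()
  Gp <- matrix(0, n + 4, m + 4)
  acc <- matrix(0, n + 2, m + 2)
  Gp[3:(n + 2), 3:(m + 2)] <- G
  for (di in -1:1) for (dj in -1:1) {
    acc <- acc + s[di + 2, dj + 2] *
      Gp[(2:(n + 3)) + di, (2:(m + 3)) + dj]
  }
  out <- acc[2:(n + 1), 2:(m + 1)]
  # fold replicated padding rows/cols onto their source edge pixels
  out[1, ] <- out[1, ] + acc[1, 2:(m + 1)]
  out[n, ] <- out[n, ] + acc[n + 2, 2:(m + 1)]
  out[, 1] <- out[, 1] + acc[2:(n + 1), 1]
  out[, m] <- out[, m] + acc[2:(n + 1), m + 2]
  out[1, 1] <- out[1, 1] + acc[1, 1]
  out[1, m] <- out[1, m] + acc[1, m + 2]
  out[n, 1] <- out[n, 1] + acc[n + 2, 1]
  out[n, m] <- out[n, m] + acc[n + 2, m + 2]
  out
}

#' Diffusion-proliferation operator G
#'
#' `G(U) = alpha * Laplacian(U) + beta * U`, combining spread and local
#' growth with the two physical coefficients.
#'
#' @param U Numeric matrix.
#' @param params [rd_params()].
#' @param boundary Boundary rule passed to [discrete_laplacian()].
#' @return Matrix of the same shape.
#' @export
diffusion_proliferation <- function(U, params, boundary = "replicate") {
  params$alpha * discrete_laplacian(U, boundary) + params$beta * U
}

#' Analytic dose-response operators
#'
#' `linear_kill_response(gamma)` returns the operator
#' `psi -> -gamma * psi`: dose-proportional first-order cell killing, used
#' as the phantom ground-truth response. `saturating_kill_response` returns
#' the bounded nonlinear variant
#' `psi -> -gamma * psi / (1 + psi / psi_half)`, whose magnitude saturates
#' at `gamma * psi_half`, for testing that a learned operator can fit a
#' non-linear response.
#'
#' @param gamma Nonnegative kill-rate coefficient.
#' @param psi_half Positive half-saturation level of `psi = D * U`.
#' @return An object of class `rd_response`: a function `psi -> matrix`
#'   with attributes `label`.
#' @export
linear_kill_response <- function(gamma = 0.4) {
  if (!is.finite(gamma) || gamma < 0)
    stop("linear_kill_response: gamma must be finite and >= 0")
  f <- function(psi) -gamma * psi
  structure(f, label = sprintf("linear_kill(gamma=%g)", gamma),
            pars = list(type = "linear", gamma = gamma),
            class = c("rd_response", "function"))
}

#' @rdname linear_kill_response
#' @export
saturating_kill_response <- function(gamma = 0.4, psi_half = 10) {
  if (!is.finite(gamma) || gamma < 0)
    stop("saturating_kill_response: gamma must be finite and >= 0")
  if (!is.finite(psi_half) || psi_half <= 0)
    stop("saturating_kill_response: psi_half must be > 0")
  f <- function(psi) -gamma * psi / (1 + psi / psi_half)
  structure(f, label = sprintf("saturating_kill(gamma=%g, psi_half=%g)",
                               gamma, psi_half),
            pars = list(type = "saturating", gamma = gamma,
                        psi_half = psi_half),
            class = c("rd_response", "function"))
}

#' Zero response operator
#' @return An `rd_response` mapping any field to zeros.
#' @export
zero_response <- function() {
  f <- function(psi) array(0, dim(psi))
  structure(f, label = "zero", pars = list(type = "zero"),
            class = c("rd_response", "function"))
}

# One Euler step decomposed into its three additive components. All solver
# code paths route through this function so trajectories are bit-identical
# across entry points.
step_components <- function(U, D, params, F_op, boundary = "replicate") {
  lap <- discrete_laplacian(U, boundary)
  resp <- F_op(D * U)
  diff_inc <- params$h * (params$alpha * lap)
  prol_inc <- params$h * (params$beta * U)
  resp_inc <- params$h * resp
  list(U_next = U + diff_inc + prol_inc + resp_inc,
       diffusion = diff_inc, proliferation = prol_inc,
       dose_response = resp_inc, laplacian = lap)
}

#' One forward-Euler step of the dose-coupled model
#'
#' `U + h * G(U) + h * F(D o U)` where `o` is the element-wise product,
#' `G` the diffusion-proliferation operator and `F` the response operator.
#'
#' @param U,D Numeric matrices of one shape (state and dose map).
#' @param params [rd_params()].
#' @param F_op An `rd_response` (or any function `psi -> matrix`).
#' @param boundary Boundary rule for the Laplacian.
#' @return The updated state matrix.
#' @export
euler_step <- function(U, D, params, F_op = zero_response(),
                       boundary = "replicate") {
  if (!identical(dim(U), dim(D)))
    stop("euler_step: U and D must have the same shape")
  step_components(U, D, params, F_op, boundary)$U_next
}

#' Simulate the model forward in time
#'
#' Iterates [euler_step()] `n_steps` times from the initial SUV state,
#' returning the full trajectory of `Nt + 1` frames at times
#' `0, h, 2h, ..., T`.
#'
#' @param U0 Initial state, a `scalar_field2d` (SUV).
#' @param D Dose map, a `scalar_field2d` on the same grid.
#' @param params [rd_params()].
#' @param F_op Response operator.
#' @param boundary Boundary rule.
#' @param clip_negative If `TRUE`, negative values are set to 0 after each
#'   step (off by default: the update rule itself has no projection; the
#'   phantom generator switches it on so ground-truth images stay valid
#'   SUV fields).
#' @return Object of class `rd_trajectory`: list with `frames` (list of
#'   `scalar_field2d`, length `Nt + 1`), `times`, `params`.
#' @examples
#' g <- grid2d(8, 8, 2.5, 2.5)
#' U0 <- scalar_field2d(matrix(1, 8, 8), g, "SUV")
#' D <- scalar_field2d(matrix(0, 8, 8), g, "dose_Gy")
#' tr <- simulate_forward(U0, D, rd_params(alpha = 0, beta = 1))
#' tr$frames[[5]]$values[1, 1]  # (1 + 0.25)^4
#' @export
simulate_forward <- function(U0, D, params, F_op = zero_response(),
                             boundary = "replicate", clip_negative = FALSE) {
  stopifnot(inherits(U0, "scalar_field2d"), inherits(D, "scalar_field2d"))
  if (!same_grid(U0$grid, D$grid))
    stop("simulate_forward: U0 and D must share one grid")
  U <- U0$values
  frames <- vector("list", params$n_steps + 1L)
  frames[[1]] <- U0
  Dm <- D$values
  for (n in seq_len(params$n_steps)) {
    U <- step_components(U, Dm, params, F_op, boundary)$U_next
    if (clip_negative) U[U < 0] <- 0
    if (any(!is.finite(U)))
      stop("simulate_forward: non-finite values at step ", n,
           " (divergence)")
    # un-clipped dynamics may legitimately undershoot zero; such frames are
    # tagged dimensionless so the container invariants stay honest
    qty <- if (any(U < 0)) "dimensionless" else U0$quantity
    frames[[n + 1]] <- scalar_field2d(U, U0$grid, qty)
  }
  structure(list(frames = frames,
                 times = params$h * (0:params$n_steps),
                 params = params),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("<rd_trajectory> %d frames, t in [0, %g], alpha=%.4g beta=%.4g\n",
              length(x$frames), max(x$times), x$params$alpha, x$params$beta))
  invisible(x)
}

#' Export a trajectory as NIfTI frames plus a JSON manifest
#' @param traj An `rd_trajectory`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_trajectory <- function(traj, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(traj$frames))
  for (k in seq_along(traj$frames)) {
    paths[k] <- file.path(dir, sprintf("%s_%02d.nii.gz", prefix, k - 1))
    write_field(traj$frames[[k]], paths[k])
  }
  man <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(times = traj$times,
                            params = unclass(traj$params),
                            frames = basename(paths)),
                       man, auto_unbox = TRUE, digits = NA)
  invisible(man)
}
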
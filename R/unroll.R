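#' Construct a trained (or analytically specified) unrolled model
#'
#' Bundles everything [forward_unrolled()] needs: the response operator
#' (a learned `response_net`, or `NULL` when an analytic operator is
#' substituted at prediction time), the two physical coefficients, the
#' Euler discretization, and the input normalization constants. [train()]
#' returns objects of this class; constructing one directly is useful for
#' simulation studies with known coefficients.
#'
#' @param net A `response_net` or `NULL`.
#' @param alpha_hat,beta_hat Physical diffusion/proliferation coefficients.
#' @param pde An [rd_params()] supplying `n_steps` and `total_time` (its
#'   own alpha/beta are ignored in favour of `alpha_hat`, `beta_hat`).
#' @param normalization List with `suv_scale` and `dose_scale`: SUV images
#'   are divided by `suv_scale` (default 10) and dose maps by `dose_scale`
#'   (default 20 Gy, the delivered maximum) before entering the network.
#' @param history Optional per-epoch loss data frame (filled by [train()]).
#' @param ... Further fields stored verbatim (e.g. `training_config`).
#' @return Object of class `rd_model`.
#' @export
rd_model <- function(net = NULL, alpha_hat, beta_hat,
                     pde = rd_params(alpha = alpha_hat, beta = beta_hat),
                     normalization = list(suv_scale = 10, dose_scale = 20),
                     history = NULL, ...) {
  if (alpha_hat < 0) stop("rd_model: alpha_hat must be >= 0")
  structure(list(net = net, alpha_hat = alpha_hat, beta_hat = beta_hat,
                 pde = pde, normalization = normalization,
                 history = history, ...),
            class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  cat(sprintf("<rd_model> alpha=%.4g beta=%.4g Nt=%d h=%g response=%s\n",
              x$alpha_hat, x$beta_hat, x$pde$n_steps, x$pde$h,
              if (is.null(x$net)) "analytic/none" else "learned network"))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs, best val loss %.6g\n",
                max(x$history$epoch), min(x$history$val_loss)))
  invisible(x)
}

#' Read back the physical coefficients of a model
#'
#' Returns the diffusion and proliferation coefficients on the physical
#' (de-normalized) scale. Because SUV normalization is a fixed linear
#' rescaling of the state and the diffusion/proliferation terms are linear
#' in the state, the coefficients learned on the normalized scale are
#' already the physical ones.
#'
#' @param model An `rd_model`.
#' @return Named numeric vector `c(alpha_hat = , beta_hat = )`.
#' @export
recover_coefficients <- function(model) {
  c(alpha_hat = model$alpha_hat, beta_hat = model$beta_hat)
}

#' Mean squared-l2 prediction loss
#'
#' `(1/m) * sum_k ||pred_k - truth_k||_2^2` with the squared norm summed
#' over pixels: the training objective of the unrolled model.
#'
#' @param predictions,truths Equal-length lists of numeric matrices with
#'   matching shapes.
#' @return Nonnegative scalar.
#' @export
l2_loss <- function(predictions, truths) {
  if (length(predictions) == 0L) stop("l2_loss: empty lists")
  if (length(predictions) != length(truths))
    stop("l2_loss: lists must have equal length")
  tot <- 0
  for (k in seq_along(predictions)) {
    if (!identical(dim(predictions[[k]]), dim(truths[[k]])))
      stop("l2_loss: shape mismatch at sample ", k)
    tot <- tot + sum((predictions[[k]] - truths[[k]])^2)
  }
  tot / length(predictions)
}

#' Predict a post-radiation image by unrolling the model
#'
#' Normalizes the inputs, applies the Euler update
#' `U <- U + h * (alpha * Lap(U) + beta * U) + h * F(D o U)` for `Nt`
#' steps with the model's response operator (the learned network in
#' inference mode, or `response_override`), and de-normalizes. The three
#' additive increments are accumulated over all steps into a breakdown
#' whose components sum to `prediction - pre` (telescoping identity).
#'
#' @param model An [rd_model()].
#' @param pre Pre-radiation SUV `scalar_field2d`.
#' @param dose Dose `scalar_field2d` on the same grid.
#' @param response_override Optional `rd_response` used instead of the
#'   model's network (operating on the normalized scale).
#' @param boundary Laplacian boundary rule.
#' @return Object of class `rd_prediction`: list with `prediction`
#'   (`scalar_field2d`, SUV), `trajectory` (`rd_trajectory`, SUV units),
#'   `normalized_frames` (list of matrices on the network scale), and
#'   `breakdown` (list of `diffusion`, `proliferation`, `dose_response`
#'   matrices in SUV units).
#' @export
forward_unrolled <- function(model, pre, dose, response_override = NULL,
                             boundary = "replicate") {
  stopifnot(inherits(model, "rd_model"))
  if (!same_grid(pre$grid, dose$grid))
    stop("forward_unrolled: pre and dose must share one grid")
  ns <- model$normalization
  if (is.null(ns$suv_scale) || is.null(ns$dose_scale))
    stop("forward_unrolled: model normalization constants missing")
  use_net <- is.null(response_override) && !is.null(model$net)
  params <- list(alpha = model$alpha_hat, beta = model$beta_hat,
                 h = model$pde$h, n_steps = model$pde$n_steps)
  U <- pre$values / ns$suv_scale
  Dn <- dose$values / ns$dose_scale
  zero <- matrix(0, nrow(U), ncol(U))
  acc <- list(diffusion = zero, proliferation = zero, dose_response = zero)
  frames_n <- vector("list", params$n_steps + 1L)
  frames_n[[1]] <- U
  for (n in seq_len(params$n_steps)) {
    F_op <- if (use_net) as_response_operator(model$net, step = n)
            else if (!is.null(response_override)) response_override
            else zero_response()
    sc <- step_components(U, Dn, params, F_op, boundary)
    U <- sc$U_next
    if (any(!is.finite(U)))
      stop("forward_unrolled: non-finite values at step ", n, " (divergence)")
    acc$diffusion <- acc$diffusion + sc$diffusion
    acc$proliferation <- acc$proliferation + sc$proliferation
    acc$dose_response <- acc$dose_response + sc$dose_response
    frames_n[[n + 1]] <- U
  }
  s <- ns$suv_scale
  frames <- lapply(frames_n, function(m)
    scalar_field2d(m * s, pre$grid,
                   if (any(m < 0)) "dimensionless" else "SUV"))
  pred <- frames[[length(frames)]]
  structure(list(
    prediction = pred,
    trajectory = structure(list(frames = frames,
                                times = params$h * (0:params$n_steps),
                                params = model$pde),
                           class = "rd_trajectory"),
    normalized_frames = frames_n,
    breakdown = lapply(acc, function(m) m * s)),
    class = "rd_prediction")
}

#' @export
print.rd_prediction <- function(x, ...) {
  cat(sprintf("<rd_prediction> %s, %d frames, breakdown range [%.3g, %.3g]\n",
              format(x$prediction$grid), length(x$trajectory$frames),
              min(vapply(x$breakdown, min, 0)),
              max(vapply(x$breakdown, max, 0))))
  invisible(x)
}
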
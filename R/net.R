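#' Configuration of the dose-response network
#'
#' The learned response operator is a small encoder-decoder convolutional
#' network with exactly 7 convolutional layers at the defaults: two 3x3
#' convolutions (each followed by batch normalization and ReLU), a 2x2
#' max-pool that doubles the channel count, two more 3x3 convolutions, a
#' 2x up-sampling, an optional skip concatenation from the full-resolution
#' path, two 3x3 convolutions back at `base_channels`, and a final 1x1
#' convolution mapping the 16-component feature to one output channel.
#'
#' @param base_channels Feature channels on the full-resolution path
#'   (default 16; doubled after pooling).
#' @param kernel_size Convolution kernel (only 3 supported).
#' @param pool_size Pooling factor (only 2 supported).
#' @param levels Resolution levels (only 2 supported: one down-sampling).
#' @param use_skip_connection Concatenate the pre-pool features onto the
#'   up-sampled features (default `TRUE`); toggling it preserves the
#'   7-layer count.
#' @param final_kernel Kernel of the output convolution (only 1 supported).
#' @return Object of class `response_net_config`.
#' @export
response_net_config <- function(base_channels = 16, kernel_size = 3,
                                pool_size = 2, levels = 2,
                                use_skip_connection = TRUE,
                                final_kernel = 1) {
  if (base_channels < 1) stop("response_net_config: base_channels must be >= 1")
  if (kernel_size != 3 || pool_size != 2 || levels != 2 || final_kernel != 1)
    stop("response_net_config: only kernel 3, pool 2, levels 2, final 1 are supported")
  structure(list(base_channels = as.integer(base_channels),
                 kernel_size = 3L, pool_size = 2L, levels = 2L,
                 use_skip_connection = isTRUE(use_skip_connection),
                 final_kernel = 1L),
            class = "response_net_config")
}

# conv layer spec table for a given config
net_layout <- function(cfg) {
  C <- cfg$base_channels
  cat_ch <- if (cfg$use_skip_connection) 3L * C else 2L * C
  list(conv1 = list(K = 3L, cin = 1L, cout = C),
       conv2 = list(K = 3L, cin = C, cout = C),
       conv3 = list(K = 3L, cin = C, cout = 2L * C),
       conv4 = list(K = 3L, cin = 2L * C, cout = 2L * C),
       conv5 = list(K = 3L, cin = cat_ch, cout = C),
       conv6 = list(K = 3L, cin = C, cout = C),
       conv7 = list(K = 1L, cin = C, cout = 1L))
}

#' Build the dose-response network
#'
#' Initializes weights with seeded He-normal draws; biases and batch-norm
#' shifts start at zero, batch-norm scales at one. The final 1x1 layer is
#' initialized to zero so a freshly built network is the zero operator and
#' the unrolled model starts as pure diffusion-proliferation dynamics.
#'
#' @param config A [response_net_config()].
#' @param seed Integer seed for the weight draws.
#' @param precision `"single"` (default; convolutions run through sgemm,
#'   the conventional deep-learning precision) or `"double"` (used by the
#'   finite-difference gradient checks, which need exact piecewise
#'   linearity).
#' @return Object of class `response_net`.
#' @export
build_response_net <- function(config = response_net_config(), seed = 0,
                               precision = c("single", "double")) {
  precision <- match.arg(precision)
  layout <- net_layout(config)
  set.seed(seed)
  params <- list()
  running <- list()
  for (nm in names(layout)) {
    l <- layout[[nm]]
    fan_in <- l$K * l$K * l$cin
    W <- if (nm == "conv7") matrix(0, fan_in, l$cout)
         else matrix(stats::rnorm(fan_in * l$cout) * sqrt(2 / fan_in),
                     fan_in, l$cout)
    params[[nm]] <- list(W = W, b = numeric(l$cout))
    if (nm != "conv7") {
      bn <- sub("conv", "bn", nm)
      params[[bn]] <- list(gamma = rep(1, l$cout), beta = numeric(l$cout))
      running[[bn]] <- list(mean = numeric(l$cout), var = rep(1, l$cout))
    }
  }
  # batch-norm running statistics are tracked per unrolled step: each of the
  # Nt applications of the shared-weight network sees a different input
  # distribution, so blending their statistics would bias inference
  structure(list(config = config, layout = layout, params = params,
                 running_template = running, running = list(),
                 bn_eps = 1e-5, bn_momentum = 0.1,
                 single = precision == "single"),
            class = "response_net")
}

#' Count the convolutional layers of a network
#' @param net A `response_net`.
#' @return Integer layer count (7 at the default configuration).
#' @export
count_conv_layers <- function(net) {
  sum(grepl("^conv", names(net$params)))
}

#' @export
print.response_net <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<response_net> %d conv layers, base %d channels, skip=%s, %d parameters\n",
              count_conv_layers(x), x$config$base_channels,
              x$config$use_skip_connection, np))
  invisible(x)
}

as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected array input")
  if (length(d) == 2L) array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) array(x, c(d[1], d[2], 1L, d[3]))
  else x
}

relu <- function(x) { x[x < 0] <- 0; x }

# running batch-norm statistics for a given unrolled step (template until
# the step has been trained)
step_running <- function(net, step) {
  if (length(net$running) >= step && !is.null(net$running[[step]]))
    net$running[[step]]
  else net$running_template
}

# conv + BN + ReLU block, training or inference mode
block_fwd <- function(x, net, conv, bn, training, cache, running) {
  p <- net$params
  z <- .conv2d_fwd(x, p[[conv]]$W, p[[conv]]$b, net$layout[[conv]]$K,
                   net$single)
  if (training) {
    bf <- .bn_fwd(z, p[[bn]]$gamma, p[[bn]]$beta, net$bn_eps)
    a <- relu(bf$y)
    cache[[conv]] <- list(x = x, z = z, mean = bf$mean, var = bf$var, a = a)
  } else {
    r <- running[[bn]]
    a <- relu(.bn_eval(z, p[[bn]]$gamma, p[[bn]]$beta, r$mean, r$var,
                       net$bn_eps))
    cache[[conv]] <- NULL
  }
  list(a = a, cache = cache)
}

# Forward pass. psi: (H, W, 1, B) tensor (or matrix / (H, W, B) array);
# step: unrolled-step index selecting the batch-norm running statistics.
# Odd spatial dims are zero-padded to even before pooling and the output is
# cropped back. Returns list(out, cache, running) -- running holds this
# step's updated batch-norm statistics when training.
net_forward <- function(psi, net, training = FALSE, step = 1L) {
  x <- as_tensor4(psi)
  d0 <- dim(x)
  pad_r <- d0[1] %% 2L; pad_c <- d0[2] %% 2L
  if (pad_r || pad_c) {
    xp <- array(0, c(d0[1] + pad_r, d0[2] + pad_c, d0[3], d0[4]))
    xp[seq_len(d0[1]), seq_len(d0[2]), , ] <- x
    x <- xp
  }
  cache <- list(in_dim = d0, pad = c(pad_r, pad_c))
  running <- step_running(net, step)
  b1 <- block_fwd(x, net, "conv1", "bn1", training, cache, running); cache <- b1$cache
  b2 <- block_fwd(b1$a, net, "conv2", "bn2", training, cache, running); cache <- b2$cache
  mp <- .maxpool2_fwd(b2$a)
  cache$pool_idx <- mp$idx; cache$pool_in_dim <- dim(b2$a)
  b3 <- block_fwd(mp$y, net, "conv3", "bn3", training, cache, running); cache <- b3$cache
  b4 <- block_fwd(b3$a, net, "conv4", "bn4", training, cache, running); cache <- b4$cache
  up <- .upsample2_fwd(b4$a)
  if (net$config$use_skip_connection) {
    du <- dim(up); ds <- dim(b2$a)
    cat_in <- array(0, c(du[1], du[2], ds[3] + du[3], du[4]))
    cat_in[, , seq_len(ds[3]), ] <- b2$a
    cat_in[, , ds[3] + seq_len(du[3]), ] <- up
    cache$skip_channels <- ds[3]
  } else {
    cat_in <- up
    cache$skip_channels <- 0L
  }
  b5 <- block_fwd(cat_in, net, "conv5", "bn5", training, cache, running); cache <- b5$cache
  b6 <- block_fwd(b5$a, net, "conv6", "bn6", training, cache, running); cache <- b6$cache
  out <- .conv2d_fwd(b6$a, net$params$conv7$W, net$params$conv7$b, 1L,
                     net$single)
  cache$conv7_in <- if (training) b6$a else NULL
  if (pad_r || pad_c) out <- out[seq_len(d0[1]), seq_len(d0[2]), , , drop = FALSE]
  dim(out) <- c(d0[1], d0[2], d0[3], d0[4])
  if (training) {
    mom <- net$bn_momentum
    for (conv in paste0("conv", 1:6)) {
      bn <- sub("conv", "bn", conv)
      cc <- cache[[conv]]
      n <- prod(dim(cc$z)[c(1, 2, 4)])
      ub <- if (n > 1) n / (n - 1) else 1
      running[[bn]]$mean <- (1 - mom) * running[[bn]]$mean + mom * cc$mean
      running[[bn]]$var <- (1 - mom) * running[[bn]]$var + mom * cc$var * ub
    }
  }
  list(out = out, cache = cache, running = running)
}

block_bwd <- function(da, net, conv, bn, cache, grads) {
  cc <- cache[[conv]]
  dz_relu <- da * (cc$a > 0)
  p <- net$params
  bb <- .bn_bwd(cc$z, dz_relu, p[[bn]]$gamma, cc$mean, cc$var, net$bn_eps)
  grads[[bn]]$gamma <- grads[[bn]]$gamma + bb$dgamma
  grads[[bn]]$beta <- grads[[bn]]$beta + bb$dbeta
  cb <- .conv2d_bwd(cc$x, p[[conv]]$W, bb$dx, net$layout[[conv]]$K,
                    net$single)
  grads[[conv]]$W <- grads[[conv]]$W + cb$dw
  grads[[conv]]$b <- grads[[conv]]$b + cb$db
  list(dx = cb$dx, grads = grads)
}

zero_grads <- function(net) {
  lapply(net$params, function(p) lapply(p, function(a) a * 0))
}

# Backward pass through one network application. dout: gradient on the
# network output, same dims as the input psi. Accumulates into `grads`
# (structure of zero_grads) and returns dpsi.
net_backward <- function(dout, net, cache, grads) {
  d0 <- cache$in_dim; pad_r <- cache$pad[1]; pad_c <- cache$pad[2]
  dy <- as_tensor4(dout)
  if (pad_r || pad_c) {
    dyp <- array(0, c(d0[1] + pad_r, d0[2] + pad_c, d0[3], d0[4]))
    dyp[seq_len(d0[1]), seq_len(d0[2]), , ] <- dy
    dy <- dyp
  }
  cb7 <- .conv2d_bwd(cache$conv7_in, net$params$conv7$W, dy, 1L, net$single)
  grads$conv7$W <- grads$conv7$W + cb7$dw
  grads$conv7$b <- grads$conv7$b + cb7$db
  b6 <- block_bwd(cb7$dx, net, "conv6", "bn6", cache, grads); grads <- b6$grads
  b5 <- block_bwd(b6$dx, net, "conv5", "bn5", cache, grads); grads <- b5$grads
  sk <- cache$skip_channels
  dcat <- b5$dx
  if (sk > 0L) {
    dskip <- dcat[, , seq_len(sk), , drop = FALSE]
    dup <- dcat[, , (sk + 1):dim(dcat)[3], , drop = FALSE]
  } else {
    dskip <- NULL
    dup <- dcat
  }
  dp <- .upsample2_bwd(dup)
  b4 <- block_bwd(dp, net, "conv4", "bn4", cache, grads); grads <- b4$grads
  b3 <- block_bwd(b4$dx, net, "conv3", "bn3", cache, grads); grads <- b3$grads
  da2 <- .maxpool2_bwd(b3$dx, cache$pool_idx, cache$pool_in_dim)
  if (!is.null(dskip)) da2 <- da2 + dskip
  b2 <- block_bwd(da2, net, "conv2", "bn2", cache, grads); grads <- b2$grads
  b1 <- block_bwd(b2$dx, net, "conv1", "bn1", cache, grads); grads <- b1$grads
  dpsi <- b1$dx
  if (pad_r || pad_c)
    dpsi <- dpsi[seq_len(d0[1]), seq_len(d0[2]), , , drop = FALSE]
  dim(dpsi) <- d0
  list(dpsi = dpsi, grads = grads)
}

#' Apply a response network to a single field
#'
#' Wraps a `response_net` as an `rd_response` operator (inference mode,
#' running batch-norm statistics), so the learned operator can be used
#' anywhere an analytic response operator is accepted.
#'
#' @param net A `response_net`.
#' @param step Unrolled-step index whose batch-norm running statistics are
#'   used (each of the `Nt` applications tracks its own).
#' @return An `rd_response` function `psi -> matrix`.
#' @export
as_response_operator <- function(net, step = 1L) {
  f <- function(psi) {
    out <- net_forward(as_tensor4(as.matrix(psi)), net, training = FALSE,
                       step = step)$out
    matrix(out, nrow(psi), ncol(psi))
  }
  structure(f, label = "learned", pars = list(type = "network"),
            class = c("rd_response", "function"))
}
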
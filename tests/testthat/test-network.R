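test_that("network obeys its architectural contract", {
  net <- build_response_net(response_net_config(), seed = 1)
  expect_identical(count_conv_layers(net), 7L)
  # channel schedule 16,16 -> 32,32 -> 16,16 -> 1 with skip concatenation
  expect_identical(ncol(net$params$conv1$W), 16L)
  expect_identical(ncol(net$params$conv4$W), 32L)
  expect_identical(nrow(net$params$conv5$W), 9L * 48L)
  expect_identical(ncol(net$params$conv7$W), 1L)
  expect_identical(nrow(net$params$conv7$W), 16L)  # 1x1 from 16 features

  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  out <- rdresponse:::net_forward(x, net, training = FALSE)$out
  expect_identical(dim(out), c(64L, 64L, 1L, 1L))
  # zero-initialized final layer: the fresh network is the zero operator
  expect_true(all(out == 0))

  # odd spatial dims are padded internally and cropped on output
  x2 <- array(rnorm(33 * 47 * 2), c(33, 47, 1, 2))
  out2 <- rdresponse:::net_forward(x2, net, training = TRUE)$out
  expect_identical(dim(out2), c(33L, 47L, 1L, 2L))
  expect_true(all(is.finite(out2)))

  # no skip connection still gives 7 layers and valid shapes
  net2 <- build_response_net(response_net_config(use_skip_connection = FALSE),
                             seed = 1)
  expect_identical(count_conv_layers(net2), 7L)
  expect_identical(nrow(net2$params$conv5$W), 9L * 32L)
  out3 <- rdresponse:::net_forward(x, net2, training = FALSE)$out
  expect_identical(dim(out3), c(64L, 64L, 1L, 1L))
})

test_that("convolution kernels match a direct reference and their own double path", {
  # forward: explicit-loop zero-padded cross-correlation in double
  ref_conv <- function(x, w, bias, K) {
    H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(w)
    pad <- K %/% 2
    y <- array(0, c(H, W, Cout, dim(x)[4]))
    for (b in seq_len(dim(x)[4])) for (co in seq_len(Cout))
      for (i in seq_len(H)) for (j in seq_len(W)) {
        acc <- bias[co]
        for (ci in seq_len(Cin)) for (kj in 1:K) for (ki in 1:K) {
          ii <- i + ki - 1 - pad; jj <- j + kj - 1 - pad
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
            acc <- acc + x[ii, jj, ci, b] *
              w[(ki - 1) + K * ((kj - 1) + K * (ci - 1)) + 1, co]
        }
        y[i, j, co, b] <- acc
      }
    y
  }
  set.seed(12)
  x <- array(rnorm(6 * 5 * 3 * 2), c(6, 5, 3, 2))
  w <- matrix(rnorm(9 * 3 * 4), 27, 4)
  bias <- rnorm(4)
  ref <- ref_conv(x, w, bias, 3L)
  expect_equal(rdresponse:::.conv2d_fwd(x, w, bias, 3L, FALSE), ref,
               tolerance = 1e-12)
  # the production single-precision path is the same computation at float32
  expect_equal(rdresponse:::.conv2d_fwd(x, w, bias, 3L, TRUE), ref,
               tolerance = 1e-5)
  dy <- array(rnorm(length(ref)), dim(ref))
  bd <- rdresponse:::.conv2d_bwd(x, w, dy, 3L, FALSE)
  bs <- rdresponse:::.conv2d_bwd(x, w, dy, 3L, TRUE)
  expect_equal(bs$dw, bd$dw, tolerance = 1e-5)
  expect_equal(bs$dx, bd$dx, tolerance = 1e-5)
  expect_equal(bs$db, bd$db, tolerance = 1e-10)
})

test_that("network gradients match finite differences through the unrolled graph", {
  set.seed(42)
  H <- 8; W <- 8; B <- 2
  # double-precision path: finite differences need exact piecewise linearity
  net <- build_response_net(response_net_config(base_channels = 2), seed = 3,
                            precision = "double")
  net$params$conv7$W <- matrix(rnorm(2) * 0.3, 2, 1)  # exercise the response path
  pde <- rd_params(alpha = 0.04, beta = -0.08, n_steps = 3, total_time = 1)
  pre <- array(abs(rnorm(H * W * B)) + 0.3, c(H, W, B))
  dose <- array(abs(rnorm(H * W * B)), c(H, W, B))
  post <- array(abs(rnorm(H * W * B)) + 0.3, c(H, W, B))
  lossf <- function(net, a, b)
    rdresponse:::unrolled_batch_grad(net, a, b, pde, pre, dose, post)$loss
  bg <- rdresponse:::unrolled_batch_grad(net, 0.04, -0.08, pde, pre, dose, post)
  eps <- 1e-6
  num_da <- (lossf(net, 0.04 + eps, -0.08) - lossf(net, 0.04 - eps, -0.08)) / (2 * eps)
  num_db <- (lossf(net, 0.04, -0.08 + eps) - lossf(net, 0.04, -0.08 - eps)) / (2 * eps)
  expect_equal(bg$d_alpha, num_da, tolerance = 1e-5)
  expect_equal(bg$d_beta, num_db, tolerance = 1e-5)
  set.seed(99)
  for (nm in c("conv1", "bn2", "conv3", "bn4", "conv5", "conv6", "conv7")) {
    for (f in names(net$params[[nm]])) {
      p <- net$params[[nm]][[f]]
      i <- sample(length(p), 1)
      np <- net
      np$params[[nm]][[f]][i] <- p[i] + eps
      lp <- lossf(np, 0.04, -0.08)
      np$params[[nm]][[f]][i] <- p[i] - eps
      lm <- lossf(np, 0.04, -0.08)
      expect_equal(bg$grads[[nm]][[f]][i], (lp - lm) / (2 * eps),
                   tolerance = 1e-4,
                   label = sprintf("gradient of %s$%s", nm, f))
    }
  }
})

test_that("l2 loss is a per-sample mean of squared pixel norms", {
  a <- matrix(1, 4, 4)
  expect_identical(l2_loss(list(a), list(a)), 0)
  b <- a; b[2, 2] <- 3
  expect_identical(l2_loss(list(b), list(a)), 4)
  expect_identical(l2_loss(list(b, a), list(a, a)), 2)
  expect_error(l2_loss(list(), list()), "empty")
  expect_error(l2_loss(list(a), list(matrix(1, 3, 3))), "shape")
  # permutation invariance
  set.seed(4)
  ps <- lapply(1:5, function(k) matrix(rnorm(16), 4, 4))
  ts <- lapply(1:5, function(k) matrix(rnorm(16), 4, 4))
  perm <- sample(5)
  expect_equal(l2_loss(ps, ts), l2_loss(ps[perm], ts[perm]))
})

test_that("forward_unrolled: identity dynamics, telescoping breakdown", {
  g <- grid2d(16, 16, 2.5, 2.5)
  set.seed(6)
  pre <- scalar_field2d(matrix(runif(256, 0.5, 4), 16, 16), g, "SUV")
  dose <- scalar_field2d(matrix(runif(256, 0, 20), 16, 16), g, "dose_Gy")

  # zeroed response net with alpha = beta = 0: prediction equals input
  net <- build_response_net(response_net_config(base_channels = 4), seed = 2)
  m0 <- rd_model(net = net, alpha_hat = 0, beta_hat = 0,
                 pde = rd_params(alpha = 0, beta = 0))
  pr0 <- forward_unrolled(m0, pre, dose)
  expect_equal(pr0$prediction$values, pre$values, tolerance = 1e-15)

  # active dynamics: breakdown sums to prediction - input
  m1 <- rd_model(net = net, alpha_hat = 0.05, beta_hat = -0.1)
  pr1 <- forward_unrolled(m1, pre, dose,
                          response_override = linear_kill_response(0.4))
  delta <- pr1$prediction$values - pre$values
  total <- pr1$breakdown$diffusion + pr1$breakdown$proliferation +
    pr1$breakdown$dose_response
  expect_lt(max(abs(total - delta)) / max(abs(delta)), 1e-5)
  expect_length(pr1$trajectory$frames, 5)
})

test_that("forward_unrolled with an analytic operator equals simulate_forward bit-for-bit", {
  g <- grid2d(16, 16, 2.5, 2.5)
  set.seed(9)
  pre <- scalar_field2d(matrix(runif(256, 0.5, 4), 16, 16), g, "SUV")
  dose <- scalar_field2d(matrix(runif(256, 0, 20), 16, 16), g, "dose_Gy")
  m <- rd_model(net = NULL, alpha_hat = 0.05, beta_hat = -0.1,
                pde = rd_params(alpha = 0.05, beta = -0.1))
  F_op <- linear_kill_response(0.4)
  pr <- forward_unrolled(m, pre, dose, response_override = F_op)
  sim <- simulate_forward(
    scalar_field2d(pre$values / 10, g, "dimensionless"),
    scalar_field2d(dose$values / 20, g, "dimensionless"),
    rd_params(alpha = 0.05, beta = -0.1), F_op)
  for (k in 1:5)
    expect_identical(pr$normalized_frames[[k]], sim$frames[[k]]$values)
})

test_that("training is seeded-deterministic and learns an easy response", {
  spec <- small_spec(seed = 1)
  ds <- generate_dataset(spec, 20)
  tcfg <- training_config(batch_size = 10, max_epochs = 4, patience = 4,
                          learning_rate = 1e-3, seed = 5)
  m1 <- train(ds$train, ds$val, response_net_config(base_channels = 8),
              rd_params(), tcfg)
  m2 <- train(ds$train, ds$val, response_net_config(base_channels = 8),
              rd_params(), tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(recover_coefficients(m1), recover_coefficients(m2))
  # optimizing an easy (linear) target: loss drops from the first epoch
  expect_lt(m1$history$val_loss[4], m1$initial_val_loss)
  # best-epoch contract: reported weights come from the best validation epoch
  expect_equal(min(m1$history$val_loss),
               m1$history$val_loss[m1$best_epoch])
})

test_that("flat validation loss triggers early stopping before max_epochs", {
  # constant pre == post with zero dose response: loss and gradients are
  # exactly zero, so validation never improves after epoch 1
  g <- grid2d(8, 8, 2.5, 2.5)
  mk <- function(id) {
    f <- scalar_field2d(matrix(2, 8, 8), g, "SUV")
    paired_case(f, scalar_field2d(matrix(5, 8, 8), g, "dose_Gy"), f,
                matrix(TRUE, 8, 8), id)
  }
  cases <- lapply(1:4, mk)
  tcfg <- training_config(batch_size = 2, max_epochs = 20, patience = 3,
                          seed = 1, init_alpha = 1e-12, init_beta = 0)
  m <- train(cases, cases[1:2], response_net_config(base_channels = 2),
             rd_params(), tcfg)
  expect_lt(nrow(m$history), 20)
  expect_identical(nrow(m$history), 1L + 3L)
})

test_that("coefficients read back on the physical scale", {
  m <- rd_model(net = NULL, alpha_hat = 0.01, beta_hat = 0)
  expect_identical(recover_coefficients(m),
                   c(alpha_hat = 0.01, beta_hat = 0))
  expect_error(rd_model(net = NULL, alpha_hat = -0.1, beta_hat = 0), "alpha")
})
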
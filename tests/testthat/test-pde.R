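test_that("nine-point stencil reproduces its defining coefficients", {
  U <- matrix(0, 5, 5); U[3, 3] <- 1
  L <- discrete_laplacian(U, "zero")
  expect_identical(L[3, 3], -3)
  expect_identical(L[2, 3], 0.5); expect_identical(L[4, 3], 0.5)
  expect_identical(L[3, 2], 0.5); expect_identical(L[3, 4], 0.5)
  expect_identical(L[2, 2], 0.25); expect_identical(L[2, 4], 0.25)
  expect_identical(L[4, 2], 0.25); expect_identical(L[4, 4], 0.25)
  expect_true(all(L[1, ] == 0) && all(L[5, ] == 0))

  s <- rdresponse:::laplacian_stencil()
  expect_identical(sum(s), 0)
  expect_identical(s, t(s))
  expect_identical(s, s[3:1, 3:1])  # 180-degree rotation
  expect_identical(s, apply(s, 1, rev))  # 90-degree rotation
})

test_that("stencil annihilates constant and affine fields", {
  for (bd in c("replicate", "periodic", "zero")) {
    L <- discrete_laplacian(matrix(5, 5, 5), bd)
    if (bd == "zero") expect_true(all(abs(L[2:4, 2:4]) < 1e-14))
    else expect_true(all(abs(L) < 1e-14))
  }
  ramp <- outer(rep(1, 6), 1:7)  # U(r, c) = c
  L <- discrete_laplacian(ramp)
  expect_true(all(abs(L[2:5, 2:6]) < 1e-13))
  expect_error(discrete_laplacian(matrix(1, 2, 5)), "3 x 3")
})

test_that("diffusion-proliferation operator combines the two terms", {
  p <- rd_params(alpha = 0, beta = 2)
  expect_equal(diffusion_proliferation(matrix(1, 5, 5), p), matrix(2, 5, 5))
  p2 <- rd_params(alpha = 0.7, beta = 1.3)
  expect_equal(diffusion_proliferation(matrix(4, 5, 5), p2), matrix(1.3 * 4, 5, 5))
  U <- matrix(0, 5, 5); U[3, 3] <- 1
  p3 <- rd_params(alpha = 1, beta = 0)
  expect_equal(diffusion_proliferation(U, p3, "zero"),
               discrete_laplacian(U, "zero"))
})

test_that("euler_step closed forms", {
  p0 <- rd_params(alpha = 0, beta = 0)
  U <- matrix(runif(25), 5, 5); D <- matrix(runif(25), 5, 5)
  expect_identical(euler_step(U, D, p0), U)

  pb <- rd_params(alpha = 0.3, beta = 1)
  expect_equal(euler_step(matrix(3, 5, 5), matrix(0, 5, 5), pb),
               matrix(3 * 1.25, 5, 5))

  pg <- rd_params(alpha = 0, beta = 0)
  out <- euler_step(matrix(2, 5, 5), matrix(0.8, 5, 5), pg,
                    linear_kill_response(1))
  expect_equal(out, matrix(2 * (1 - 0.25 * 0.8), 5, 5))
  expect_error(euler_step(U, matrix(0, 4, 4), p0), "shape")
})

test_that("pure proliferation follows (1 + h beta)^Nt and converges at order 1", {
  U0 <- const_field(1)
  D <- const_field(0, quantity = "dose_Gy")
  tr <- simulate_forward(U0, D, rd_params(alpha = 0, beta = 1))
  expect_length(tr$frames, 5)
  expect_equal(tr$times, c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(abs(tr$frames[[5]]$values - 2.44140625) < 1e-12 * 2.44140625))

  # halving h: error against e^(beta T) shrinks at observed order ~1
  errs <- vapply(c(4, 8, 16, 32, 64), function(nt) {
    trn <- simulate_forward(U0, D, rd_params(alpha = 0, beta = 1, n_steps = nt))
    abs(trn$frames[[nt + 1]]$values[1, 1] - exp(1))
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.8 & orders < 1.2))
})

test_that("pure diffusion on a periodic domain conserves total intensity", {
  set.seed(3)
  U0 <- field_of(matrix(runif(144, 0.5, 3), 12, 12))
  D <- field_of(matrix(0, 12, 12), quantity = "dose_Gy")
  p <- rd_params(alpha = 0.4, beta = 0)
  tr <- simulate_forward(U0, D, p, boundary = "periodic")
  s0 <- sum(U0$values)
  for (f in tr$frames)
    expect_lt(abs(sum(f$values) - s0) / s0, 1e-10)
  # nonnegative update weights: extrema contract
  expect_lte(max(tr$frames[[5]]$values), max(U0$values) + 1e-12)
  expect_gte(min(tr$frames[[5]]$values), min(U0$values) - 1e-12)
})

test_that("euler_step is linear in U for linear response operators", {
  set.seed(8)
  p <- rd_params(alpha = 0.2, beta = -0.3)
  F_op <- linear_kill_response(0.6)
  D <- matrix(runif(36), 6, 6)
  U1 <- matrix(runif(36), 6, 6); U2 <- matrix(runif(36), 6, 6)
  a <- 1.7; b <- -0.4
  lhs <- euler_step(a * U1 + b * U2, D, p, F_op)
  rhs <- a * euler_step(U1, D, p, F_op) + b * euler_step(U2, D, p, F_op)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("simulate_forward matches an explicit per-pixel summation oracle", {
  set.seed(13)
  U0 <- field_of(matrix(runif(16, 0.5, 2), 4, 4))
  D <- field_of(matrix(runif(16), 4, 4), quantity = "dimensionless")
  p <- rd_params(alpha = 0.06, beta = -0.15)
  tr <- simulate_forward(U0, D, p, linear_kill_response(0.5))
  oracle <- brute_simulate(U0$values, D$values, 0.06, -0.15, 0.25, 4,
                           gamma = 0.5)
  expect_equal(tr$frames[[5]]$values, oracle, tolerance = 1e-12)
})

test_that("response operators follow their stated forms and bounds", {
  z <- linear_kill_response(0)
  expect_identical(z(matrix(2, 3, 3)), matrix(0, 3, 3))
  l <- linear_kill_response(1)
  expect_identical(l(matrix(2, 3, 3)), matrix(-2, 3, 3))

  # constant-field simulation matches the scalar recurrence u(1 + h b - h g d)
  U0 <- const_field(2); D <- const_field(0.8, quantity = "dose_Gy")
  p <- rd_params(alpha = 0.3, beta = 0.1)
  tr <- simulate_forward(U0, D, p, linear_kill_response(0.5))
  u <- 2
  for (k in 1:4) u <- u * (1 + 0.25 * 0.1 - 0.25 * 0.5 * 0.8)
  expect_equal(tr$frames[[5]]$values[4, 4], u, tolerance = 1e-12)

  s <- saturating_kill_response(1, psi_half = 2)
  expect_identical(s(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(s(matrix(2, 3, 3)), matrix(-1, 3, 3))  # -psi_half/2 at psi_half
  expect_true(all(abs(s(matrix(1e9, 3, 3))) <= 1 * 2))
  expect_error(saturating_kill_response(1, psi_half = 0), "psi_half")
})

test_that("parameter container validates and warns about stability", {
  expect_error(rd_params(alpha = -0.1), "alpha")
  expect_error(rd_params(n_steps = 0), "n_steps")
  expect_warning(rd_params(alpha = 2, n_steps = 4), "1/3")
  expect_silent(rd_params(alpha = 1.3, n_steps = 4))  # h*alpha = 0.325
  p <- rd_params(n_steps = 4, total_time = 1)
  expect_identical(p$h, 0.25)
})

test_that("laplacian adjoint satisfies the inner-product identity", {
  set.seed(21)
  for (bd in c("replicate", "periodic", "zero")) {
    u <- matrix(rnorm(48), 6, 8); v <- matrix(rnorm(48), 6, 8)
    expect_equal(sum(discrete_laplacian(u, bd) * v),
                 sum(u * rdresponse:::laplacian_adjoint(v, bd)),
                 tolerance = 1e-12)
  }
})

test_that("divergent simulations fail loudly with the step named", {
  U0 <- const_field(1e150)
  D <- const_field(0, quantity = "dose_Gy")
  p <- suppressWarnings(rd_params(alpha = 0, beta = 1e200, n_steps = 3))
  expect_error(simulate_forward(U0, D, p), "step")
})
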
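test_that("Otsu separates a bimodal field and matches the exhaustive oracle", {
  g <- grid2d(16, 16)
  v <- matrix(1.0, 16, 16); v[5:10, 5:10] <- 5.0
  f <- scalar_field2d(v, g, "SUV")
  ot <- otsu_threshold(f)
  expect_gt(ot$threshold, 1.0); expect_lt(ot$threshold, 5.0)
  expect_identical(ot$high_uptake_mask, v > ot$threshold)

  # exhaustive between-class-variance maximizer agrees on varied histograms
  set.seed(31)
  for (rep in 1:5) {
    x <- c(rnorm(150, 1, 0.2), rnorm(80, 4, 0.6), runif(40, 0, 6))
    x <- pmax(x, 0)
    fld <- scalar_field2d(matrix(x[1:256], 16, 16), g, "SUV")
    ot2 <- otsu_threshold(fld)
    expect_equal(ot2$threshold, brute_otsu(fld$values[matrix(TRUE, 16, 16)]),
                 tolerance = 1e-12)
  }

  # shift equivariance up to bin quantization
  fld <- scalar_field2d(matrix(pmax(c(rnorm(128, 1, 0.2), rnorm(128, 4, 0.5)), 0),
                               16, 16), g, "SUV")
  t0 <- otsu_threshold(fld)$threshold
  shifted <- scalar_field2d(fld$values + 2.5, g, "SUV")
  t1 <- otsu_threshold(shifted)$threshold
  bin_w <- diff(range(fld$values)) / 256
  expect_lt(abs((t1 - t0) - 2.5), 2 * bin_w)

  expect_error(otsu_threshold(scalar_field2d(matrix(1, 16, 16), g, "SUV")),
               "constant")
})

test_that("masked SUV mean is the arithmetic mean of in-mask pixels", {
  f <- const_field(2, 4)
  expect_identical(suv_mean(f, matrix(TRUE, 4, 4)), 2)
  v <- matrix(0, 4, 4); v[1, 1:3] <- c(1, 2, 3)
  f2 <- field_of(v)
  m <- matrix(FALSE, 4, 4); m[1, 1:3] <- TRUE
  expect_identical(suv_mean(f2, m), 2)
  single <- matrix(FALSE, 4, 4); single[1, 2] <- TRUE
  expect_identical(suv_mean(f2, single), 2)
  expect_error(suv_mean(f2, matrix(FALSE, 4, 4)), "empty")
})

test_that("Dice coefficient: identity, disjoint, partial, symmetry", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[2:3, 1:2] <- TRUE  # |a|=|b|=4, overlap 2
  expect_identical(dice(a, c2), 0.5)
  expect_identical(dice(a, c2), dice(c2, a))
  expect_warning(res <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "empty")
  expect_identical(res, 1.0)
})

test_that("gamma of an image against itself is zero with 100% passing", {
  set.seed(17)
  f <- field_of(matrix(runif(256, 0.5, 4), 16, 16))
  mask <- matrix(TRUE, 16, 16)
  gr <- gamma_index_2d(f, f, mask)
  expect_true(all(gr$gamma_map == 0))
  expect_identical(gr$passing_rate, 100)
})

test_that("flat intensity offsets give the closed-form gamma value", {
  ref <- const_field(2, 16)
  mask <- matrix(TRUE, 16, 16)
  crit <- gamma_criteria(5, 5)
  tol_abs <- 0.05 * 2
  ev <- const_field(2 + 0.5 * tol_abs, 16)
  gr <- gamma_index_2d(ref, ev, mask, crit)
  expect_true(all(abs(gr$gamma_map - 0.5) < 1e-12))
  expect_identical(gr$passing_rate, 100)
  # exactly at tolerance: gamma = 1 fails the strict < 1 criterion
  ev2 <- const_field(2 + tol_abs, 16)
  gr2 <- gamma_index_2d(ref, ev2, mask, crit)
  expect_identical(gr2$passing_rate, 0)
})

test_that("small translations pass within DTA and fail far beyond it", {
  g <- grid2d(32, 32, 2.5, 2.5)
  base <- matrix(1, 32, 32)
  sq <- function(r0, c0) {
    v <- base; v[r0:(r0 + 3), c0:(c0 + 3)] <- 5; v
  }
  ref <- scalar_field2d(sq(14, 14), g, "SUV")
  mask <- matrix(TRUE, 32, 32)
  crit <- gamma_criteria(5, 5)
  # 1-pixel shift = 2.5 mm < 5 mm DTA: everything passes
  ev_near <- scalar_field2d(sq(15, 14), g, "SUV")
  expect_identical(gamma_index_2d(ref, ev_near, mask, crit)$passing_rate, 100)
  # 6-pixel shift = 15 mm = 3x DTA: edge pixels of the feature fail
  ev_far <- scalar_field2d(sq(20, 14), g, "SUV")
  gr <- gamma_index_2d(ref, ev_far, mask, crit)
  expect_lt(gr$passing_rate, 100)
  expect_gte(gr$gamma_map[14, 14], 1)
})

test_that("gamma implementation equals the brute-force all-pairs oracle", {
  set.seed(23)
  g <- grid2d(24, 24, 2.5, 2.5)
  smooth <- function() {
    z <- matrix(rnorm(36), 6, 6)
    f <- resample_bilinear(scalar_field2d(z, grid2d(6, 6, 10, 10),
                                          "dimensionless"), grid2d(24, 24, 2.5, 2.5))
    f$values - min(f$values) + 0.5
  }
  ref <- scalar_field2d(smooth(), g, "SUV")
  ev <- scalar_field2d(pmax(ref$values + 0.15 * matrix(rnorm(576), 24, 24), 0),
                       g, "SUV")
  mask <- ellipse <- rdresponse:::ellipse_mask(g, c(0.9, 0.9))
  for (crit in list(gamma_criteria(5, 5), gamma_criteria(10, 5),
                    gamma_criteria(3, 10, normalization = "local"))) {
    gr <- gamma_index_2d(ref, ev, mask, crit)
    oracle <- brute_gamma(ref$values, ev$values, mask,
                          crit$intensity_tol_percent, crit$dta_mm,
                          c(2.5, 2.5), cap = crit$gamma_cap,
                          normalization = crit$normalization)
    expect_lt(max(abs(gr$gamma_map - oracle), na.rm = TRUE), 1e-10)
  }
})

test_that("passing rate is monotone as tolerances loosen", {
  set.seed(29)
  spec <- small_spec(seed = 12)
  case <- generate_case(spec, 2)
  ev <- scalar_field2d(pmax(case$post$values +
                              0.12 * matrix(rnorm(1024), 32, 32) *
                              case$body_mask, 0),
                       case$post$grid, "SUV")
  p55 <- gamma_index_2d(case$post, ev, case$body_mask, gamma_criteria(5, 5))
  p510 <- gamma_index_2d(case$post, ev, case$body_mask, gamma_criteria(5, 10))
  p105 <- gamma_index_2d(case$post, ev, case$body_mask, gamma_criteria(10, 5))
  p1010 <- gamma_index_2d(case$post, ev, case$body_mask, gamma_criteria(10, 10))
  expect_gte(p510$passing_rate, p55$passing_rate)
  expect_gte(p105$passing_rate, p55$passing_rate)
  expect_gte(p1010$passing_rate, p510$passing_rate)
  expect_gte(p1010$passing_rate, p105$passing_rate)
})

test_that("sub-pixel upsampling never increases gamma", {
  set.seed(37)
  spec <- small_spec(seed = 14)
  case <- generate_case(spec, 1)
  ev <- scalar_field2d(pmax(case$post$values + 0.1 *
                              matrix(rnorm(1024), 32, 32) * case$body_mask, 0),
                       case$post$grid, "SUV")
  g1 <- gamma_index_2d(case$post, ev, case$body_mask,
                       gamma_criteria(5, 5, upsample_factor = 1))
  g3 <- gamma_index_2d(case$post, ev, case$body_mask,
                       gamma_criteria(5, 5, upsample_factor = 3))
  expect_true(all(g3$gamma_map <= g1$gamma_map + 1e-12, na.rm = TRUE))
  expect_gte(g3$passing_rate, g1$passing_rate)
})

test_that("cohort evaluation of perfect predictions is perfect and consistent", {
  spec <- small_spec(seed = 15)
  cases <- lapply(1:4, function(k) generate_case(spec, k))
  preds <- lapply(cases, function(cs) cs$post)
  rep <- evaluate_cohort(cases, preds)
  expect_identical(nrow(rep$rows), 4L)
  expect_true(all(rep$rows$dice == 1))
  for (l in names(rep$summary$passing_rate)) {
    col <- rep$rows[[paste0("passing_", l)]]
    expect_true(all(col == 100))
    # summary recomputable from rows
    expect_identical(rep$summary$passing_rate[[l]][["median"]], median(col))
    expect_identical(rep$summary$passing_rate[[l]][["mean"]], mean(col))
  }
  expect_equal(rep$rows$suv_mean_pred, rep$rows$suv_mean_truth)
  expect_identical(rep$summary$dice[["mean"]], 1)

  # a failing slice is recorded with a reason, not dropped silently
  bad <- cases
  bad[[2]]$post <- NULL
  rep2 <- evaluate_cohort(bad, preds)
  expect_identical(nrow(rep2$rows), 3L)
  expect_identical(nrow(rep2$failed), 1L)
  expect_match(rep2$failed$reason, "post")
})

test_that("gamma error conditions are reported", {
  f <- const_field(0, 8, quantity = "dimensionless")
  z <- scalar_field2d(matrix(0, 8, 8), grid2d(8, 8, 2.5, 2.5), "SUV")
  expect_error(gamma_index_2d(z, z, matrix(TRUE, 8, 8)), "all-zero")
  expect_error(gamma_criteria(0, 5), "positive")
  expect_error(gamma_criteria(5, 5, gamma_cap = 0.5), "cap")
})
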
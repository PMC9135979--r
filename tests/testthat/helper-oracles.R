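# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (explicit loops, exhaustive search) so they share no
# code with the implementations they check.

# all-pairs gamma search: for every in-mask reference pixel, minimize over
# every evaluated pixel of the whole image
brute_gamma <- function(ref, ev, mask, intensity_pct, dta_mm, spacing_mm,
                        cap = 2, normalization = "global_max") {
  H <- nrow(ref); W <- ncol(ref)
  coords <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  pos_mm <- (coords - 1) %*% diag(spacing_mm)
  ev_vec <- as.vector(ev)
  gmap <- matrix(NA_real_, H, W)
  ref_max <- max(ref[mask])
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    tol <- if (normalization == "global_max") intensity_pct / 100 * ref_max
           else intensity_pct / 100 * ref[i, j]
    p <- c((i - 1) * spacing_mm[1], (j - 1) * spacing_mm[2])
    d2 <- (pos_mm[, 1] - p[1])^2 + (pos_mm[, 2] - p[2])^2
    dI <- ev_vec - ref[i, j]
    it <- if (tol > 0) (dI / tol)^2 else ifelse(dI == 0, 0, Inf)
    gmap[i, j] <- min(cap, sqrt(min(it + d2 / dta_mm^2)))
  }
  gmap
}

# exhaustive Otsu: evaluate between-class variance at every candidate bin
# edge directly from histogram counts and midpoints
brute_otsu <- function(x, n_bins = 256) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best_t <- NA; best_v <- -Inf
  for (t in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts[(t + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:t] * mids[1:t]) / n0
    m1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n1
    v <- (n0 / length(x)) * (n1 / length(x)) * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  breaks[best_t + 1]
}

# per-pixel stencil summation with replicate boundary: an explicit-loop
# simulator for tiny grids
brute_simulate <- function(U0, D, alpha, beta, h, n_steps, gamma = 0) {
  n <- nrow(U0); m <- ncol(U0)
  s <- matrix(c(1/4, 1/2, 1/4, 1/2, -3, 1/2, 1/4, 1/2, 1/4), 3, 3)
  clampi <- function(i, n) min(max(i, 1), n)
  U <- U0
  for (step in seq_len(n_steps)) {
    L <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1)
        acc <- acc + s[di + 2, dj + 2] * U[clampi(i + di, n), clampi(j + dj, m)]
      L[i, j] <- acc
    }
    U <- U + h * (alpha * L) + h * (beta * U) + h * (-gamma * D * U)
  }
  U
}

field_of <- function(values, spacing = c(2.5, 2.5), quantity = "SUV") {
  scalar_field2d(values, grid2d(nrow(values), ncol(values),
                                spacing[1], spacing[2]), quantity)
}

const_field <- function(v, n = 8, spacing = c(2.5, 2.5), quantity = "SUV") {
  field_of(matrix(v, n, n), spacing, quantity)
}

# small fast phantom spec for unit tests (full 64x64 is exercised in the
# acceptance tests)
small_spec <- function(seed = 7, ...) {
  phantom_spec(grid = grid2d(32, 32, 2.5, 2.5),
               n_hotspots = c(1, 2),
               seed = seed, ...)
}
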
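# Shared fixtures: band-limited random fields, analytic velocities, and
# independent spectral oracles built on stats::fft (the package's own
# spectral path uses FFTW, so these stay an independent route).

coords <- function(grid) velreg:::grid_coord_arrays(grid)

# Random band-limited smooth scalar field (modes up to kmax).
rand_smooth <- function(grid, kmax = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- coords(grid)
  f <- array(0, grid$dims)
  for (k in seq_len(kmax)) {
    f <- f + rnorm(1, 0, 1 / k) * sin(k * co[[1]] + runif(1, 0, 2 * pi)) *
      cos(k * co[[2]] + runif(1, 0, 2 * pi)) +
      rnorm(1, 0, 1 / k) * cos(k * co[[3]] + runif(1, 0, 2 * pi))
  }
  f
}

rand_smooth_vf <- function(grid, amp = 1, kmax = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- vector_field(grid)
  for (a in 1:3) v[, , , a] <- amp * rand_smooth(grid, kmax)
  v
}

# Independent spectral oracle for the regularization operator, built directly
# from its per-mode matrix with stats::fft.
reg_apply_oracle <- function(v, grid, beta_v, beta_w) {
  sp <- velreg:::grid_spectra(grid)
  vhat <- list(stats::fft(v[, , , 1]), stats::fft(v[, , , 2]), stats::fft(v[, , , 3]))
  kdotv <- sp$kd[[1]] * vhat[[1]] + sp$kd[[2]] * vhat[[2]] + sp$kd[[3]] * vhat[[3]]
  out <- array(0, dim = c(grid$dims, 3))
  for (a in 1:3) {
    rhat <- beta_v * sp$ksq * vhat[[a]] + beta_w * (1 + sp$ksq) * sp$kd[[a]] * kdotv
    out[, , , a] <- Re(stats::fft(rhat, inverse = TRUE)) / grid$n
  }
  out
}

# Spectral Laplacian oracle.
laplacian_oracle <- function(f, grid) {
  sp <- velreg:::grid_spectra(grid)
  Re(stats::fft(-sp$ksq * stats::fft(f), inverse = TRUE)) / grid$n
}

l2i <- function(a, b, grid) velreg:::l2_inner(a, b, grid)

# Divergence-free analytic velocity (2D cellular flow, constant in x3).
divfree_vf <- function(grid, amp = 1) {
  co <- coords(grid)
  v <- vector_field(grid)
  v[, , , 1] <- amp * sin(co[[1]]) * cos(co[[2]])
  v[, , , 2] <- -amp * cos(co[[1]]) * sin(co[[2]])
  v
}
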
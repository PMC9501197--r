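test_that("fd_gradient matches analytic derivatives at 8th order", {
  g <- make_grid(c(32, 32, 32))
  co <- coords(g)

  # constant field -> exactly zero
  expect_equal(max(abs(fd_gradient(scalar_field(g, 3.7), g))), 0)

  gr <- fd_gradient(sin(co[[1]]), g)
  expect_lt(max(abs(gr[, , , 1] - cos(co[[1]]))), 1e-8)
  expect_equal(max(abs(gr[, , , 2])), 0)

  gr3 <- fd_gradient(sin(3 * co[[2]]), g)
  expect_lt(max(abs(gr3[, , , 2] - 3 * cos(3 * co[[2]]))), 1e-4)
  expect_equal(max(abs(gr3[, , , 1])), 0)
  expect_equal(max(abs(gr3[, , , 3])), 0)

  # observed convergence order 8 +/- 0.5 when N doubles
  g2 <- make_grid(c(64, 16, 16))
  co2 <- coords(g2)
  e1 <- max(abs(fd_gradient(sin(3 * co[[1]]), g)[, , , 1] - 3 * cos(3 * co[[1]])))
  e2 <- max(abs(fd_gradient(sin(3 * co2[[1]]), g2)[, , , 1] - 3 * cos(3 * co2[[1]])))
  expect_gt(log2(e1 / e2), 7.5)
  expect_lt(log2(e1 / e2), 8.5)

  expect_error(fd_gradient(scalar_field(g, 1) + NA, g), "non-finite")
})

test_that("fd_divergence matches analytic and spectral-Laplacian oracles", {
  g <- make_grid(c(32, 32, 32))
  co <- coords(g)
  u <- vector_field(g)
  u[, , , 1] <- 1.1; u[, , , 2] <- -2; u[, , , 3] <- 0.5
  expect_equal(max(abs(fd_divergence(u, g))), 0)

  u2 <- vector_field(g)
  u2[, , , 1] <- sin(co[[1]])
  expect_lt(max(abs(fd_divergence(u2, g) - cos(co[[1]]))), 1e-8)

  f <- rand_smooth(g, kmax = 2, seed = 11)
  lap_fd <- fd_divergence(fd_gradient(f, g), g)
  expect_lt(max(abs(lap_fd - laplacian_oracle(f, g))) / max(abs(f)), 1e-4)
})

test_that("gradient and divergence are skew-adjoint on the periodic grid", {
  g <- make_grid(c(16, 12, 16))
  set.seed(5)
  for (rep in 1:3) {
    f <- rand_smooth(g, 3)
    u <- rand_smooth_vf(g, kmax = 3)
    s <- l2i(fd_gradient(f, g), u, g) + l2i(f, fd_divergence(u, g), g)
    scale <- velreg:::l2_norm(f, g) * velreg:::l2_norm(u, g)
    expect_lt(abs(s) / scale, 1e-10)
  }
})

test_that("apply_reg_gradient matches the per-mode matrix oracle and hand values", {
  g <- make_grid(c(16, 16, 16))
  co <- coords(g)
  p <- reg_params(0.7, 0.3)

  expect_equal(max(abs(apply_reg_gradient(vector_field(g, 2), g, p))), 0)

  # divergence-free single mode |k|^2 = 1: beta_w term vanishes
  v <- vector_field(g)
  v[, , , 1] <- sin(co[[2]])
  expect_lt(max(abs(apply_reg_gradient(v, g, p) - 0.7 * v)), 1e-12)

  # gradient-of-scalar mode: both contributions, against the fft oracle
  v2 <- vector_field(g)
  v2[, , , 1] <- cos(co[[1]])
  r <- apply_reg_gradient(v2, g, p)
  oracle <- reg_apply_oracle(v2, g, 0.7, 0.3)
  expect_lt(max(abs(r - oracle)), 1e-10)
  # hand value: mode k = (1,0,0), r = [bv |k|^2 + bw (1+|k|^2) ] v
  expect_lt(max(abs(r[, , , 1] - (0.7 + 0.3 * 2) * cos(co[[1]]))), 1e-10)

  # random fields against the independent stats::fft oracle
  set.seed(9)
  v3 <- rand_smooth_vf(g, kmax = 3)
  expect_lt(max(abs(apply_reg_gradient(v3, g, p) - reg_apply_oracle(v3, g, 0.7, 0.3))),
            1e-10 * max(abs(v3)))
  expect_error(apply_reg_gradient(v3, g, reg_params(-1, 0)), "beta_v")
})

test_that("regularization operator is self-adjoint and positive semidefinite", {
  g <- make_grid(c(12, 16, 12))
  set.seed(3)
  p <- reg_params(0.2, 0.6)
  for (rep in 1:3) {
    u <- rand_smooth_vf(g, kmax = 3)
    w <- rand_smooth_vf(g, kmax = 3)
    ru <- apply_reg_gradient(u, g, p)
    rw <- apply_reg_gradient(w, g, p)
    expect_lt(abs(l2i(ru, w, g) - l2i(u, rw, g)) / abs(l2i(ru, w, g)), 1e-10)
    expect_gte(l2i(ru, u, g), 0)
  }
})

test_that("invert_reg_operator is the exact inverse off the zero mode", {
  g <- make_grid(c(16, 12, 16))
  p <- reg_params(0.37, 0.11)
  set.seed(21)
  v <- rand_smooth_vf(g, kmax = 3) + 1.5 # nonzero mean
  back <- invert_reg_operator(apply_reg_gradient(v, g, p), g, p)
  vc <- v
  for (a in 1:3) vc[, , , a] <- v[, , , a] - mean(v[, , , a])
  expect_lt(max(abs(back - vc)) / max(abs(vc)), 1e-10)

  # constant fields pass through unchanged (zero-mode identity)
  expect_equal(invert_reg_operator(vector_field(g, -2.5), g, p),
               vector_field(g, -2.5), tolerance = 1e-12)

  # beta_w = 0, divergence-free mode |k|^2 = 4: division by 4 beta_v
  co <- coords(g)
  b <- vector_field(g)
  b[, , , 1] <- sin(2 * co[[2]])
  p0 <- reg_params(0.25, 0)
  expect_lt(max(abs(invert_reg_operator(b, g, p0) - b / (4 * 0.25))), 1e-12)
})

test_that("spectral prolongation is exact for band-limited fields and conserves the mean", {
  g16 <- make_grid(c(16, 16, 16))
  g32 <- make_grid(c(32, 32, 32))
  co16 <- coords(g16)
  co32 <- coords(g32)

  f <- sin(co16[[1]])
  up <- spectral_prolong(f, g16, g32)
  expect_lt(max(abs(up - sin(co32[[1]]))), 1e-12)

  expect_equal(spectral_prolong(scalar_field(g16, 2.2), g16, g32),
               scalar_field(g32, 2.2), tolerance = 1e-12)

  set.seed(8)
  f2 <- rand_smooth(g16, 3) + array(rnorm(g16$n, 0, 0.05), g16$dims)
  up2 <- spectral_prolong(f2, g16, g32)
  expect_lt(abs(mean(up2) - mean(f2)), 1e-13)
  back <- spectral_restrict(up2, g32, g16)
  expect_lt(max(abs(back - f2)), 1e-11)

  # anisotropic target and vector fields work too
  g_an <- make_grid(c(32, 16, 24))
  v <- rand_smooth_vf(g16, kmax = 2, seed = 2)
  vu <- spectral_prolong(v, g16, g_an)
  expect_equal(dim(vu), c(g_an$dims, 3L))
  expect_error(spectral_prolong(f, g16, make_grid(c(8, 16, 16))), "at least as large")
})

test_that("nearest-neighbor downsampling decimates on the index-0 lattice", {
  g <- make_grid(c(8, 8, 8))
  f <- array(seq_len(g$n), g$dims)
  expect_identical(downsample_nn(f, 1), f)
  d <- downsample_nn(f, 2)
  expect_equal(dim(d), c(4L, 4L, 4L))
  expect_equal(d[2, 3, 1], f[3, 5, 1])

  lab <- array(sample(0:10, g$n, replace = TRUE), g$dims)
  dl <- downsample_nn(lab, 4)
  expect_true(all(dl %in% lab))
  expect_error(downsample_nn(f, 3), "divide")
})
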
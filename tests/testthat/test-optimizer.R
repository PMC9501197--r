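test_that("objective evaluates mismatch and regularization terms correctly", {
  g <- make_grid(c(16, 16, 16))
  co <- coords(g)
  p <- reg_params(0.4, 0.1)
  cfg <- solver_config(nt = 4)
  m0 <- rand_smooth(g, 2, seed = 1)

  ob <- objective(vector_field(g), m0, m0, g, p, cfg)
  expect_equal(ob$total, 0)

  m1 <- rand_smooth(g, 2, seed = 2)
  ob2 <- objective(vector_field(g), m0, m1, g, p, cfg)
  expect_equal(ob2$mismatch, 0.5 * sum((m0 - m1)^2) * g$voxvol)
  expect_equal(ob2$reg_v, 0)
  expect_equal(ob2$reg_w, 0)

  # single divergence-free Fourier mode: reg_v = (beta_v/2) |k|^2 ||v||^2
  v <- vector_field(g)
  v[, , , 1] <- sin(2 * co[[2]])
  ob3 <- objective(v, m0, m1, g, reg_params(0.4, 0), cfg)
  expect_equal(ob3$reg_v, 0.5 * 0.4 * 4 * sum(v^2) * g$voxvol, tolerance = 1e-10)
  expect_equal(ob3$reg_w, 0)

  # reg energies agree with the quadratic form of the operator (independent route)
  vv <- rand_smooth_vf(g, seed = 3)
  ob4 <- objective(vv, m0, m1, g, p, cfg)
  quad <- 0.5 * l2i(reg_apply_oracle(vv, g, p$beta_v, p$beta_w), vv, g)
  expect_equal(ob4$reg_v + ob4$reg_w, quad, tolerance = 1e-10)
})

test_that("reduced gradient matches central finite differences of the objective", {
  g <- make_grid(c(24, 24, 24))
  p <- reg_params(1e-2, 1e-4)
  cfg <- solver_config(nt = 4)
  m0 <- rand_smooth(g, 2, seed = 7)
  m1 <- rand_smooth(g, 2, seed = 8)
  v <- rand_smooth_vf(g, amp = 0.4, seed = 9)
  gr <- reduced_gradient(v, m0, m1, g, p, cfg)
  for (i in 1:3) {
    u <- rand_smooth_vf(g, amp = 1, seed = 100 + i)
    eps <- 1e-4
    fd <- (objective(v + eps * u, m0, m1, g, p, cfg)$total -
             objective(v - eps * u, m0, m1, g, p, cfg)$total) / (2 * eps)
    expect_lt(abs(fd - l2i(gr, u, g)) / abs(fd), 1e-5)
  }
  # identical images at v = 0: gradient vanishes identically
  g0 <- reduced_gradient(vector_field(g), m0, m0, g, p, cfg)
  expect_equal(max(abs(g0)), 0)
})

test_that("continuity-adjoint gradient agrees with the discrete adjoint to discretization order", {
  g <- make_grid(c(32, 32, 32))
  p <- reg_params(1e-2, 1e-4)
  cfg <- solver_config(nt = 8)
  m0 <- rand_smooth(g, 2, seed = 17)
  m1 <- rand_smooth(g, 2, seed = 18)
  v <- rand_smooth_vf(g, amp = 0.4, seed = 19)
  gd <- reduced_gradient(v, m0, m1, g, p, cfg)
  gc <- reduced_gradient(v, m0, m1, g, p, cfg, method = "continuity")
  expect_lt(velreg:::l2_norm(gd - gc, g) / velreg:::l2_norm(gd, g), 0.1)

  # at v = 0 the continuity route has the closed form (m1 - m0) grad m0
  gz <- reduced_gradient(vector_field(g), m0, m1, g, p, cfg, method = "continuity")
  closed <- fd_gradient(m0, g) * as.numeric(m1 - m0)
  expect_lt(max(abs(gz - closed)), 1e-10)
})

test_that("Gauss-Newton Hessian matvec is symmetric, PSD, and zero on zero input", {
  g <- make_grid(c(16, 16, 16))
  p <- reg_params(1e-2, 1e-4)
  cfg <- solver_config(nt = 4)
  m0 <- rand_smooth(g, 2, seed = 27)
  m1 <- rand_smooth(g, 2, seed = 28)
  v <- rand_smooth_vf(g, amp = 0.4, seed = 29)
  expect_equal(max(abs(hessian_matvec(vector_field(g), v, m0, m1, g, p, cfg))), 0)
  for (i in 1:3) {
    u <- rand_smooth_vf(g, seed = 200 + i)
    w <- rand_smooth_vf(g, seed = 300 + i)
    hu <- hessian_matvec(u, v, m0, m1, g, p, cfg)
    hw <- hessian_matvec(w, v, m0, m1, g, p, cfg)
    s1 <- l2i(hu, w, g); s2 <- l2i(u, hw, g)
    expect_lt(abs(s1 - s2) / max(abs(s1), abs(s2)), 1e-8)
    expect_gte(l2i(hu, u, g), -1e-10)
  }
})

test_that("PCG solves SPD systems and exploits an exact preconditioner", {
  g <- make_grid(c(12, 12, 12))
  p <- reg_params(0.3, 0.2)
  rhs <- rand_smooth_vf(g, seed = 40)
  rhs0 <- rhs
  for (a in 1:3) rhs0[, , , a] <- rhs[, , , a] - mean(rhs[, , , a])

  # zero right-hand side: zero iterations
  z <- pcg(function(u) u, vector_field(g), function(r) r)
  expect_equal(z$iterations, 0L)
  expect_equal(max(abs(z$x)), 0)

  # pure regularization operator with its exact inverse as preconditioner
  sol <- pcg(function(u) apply_reg_gradient(u, g, p), rhs0,
             function(r) invert_reg_operator(r, g, p), tol = 1e-10, maxit = 10)
  expect_lte(sol$iterations, 2L)
  expect_lt(max(abs(apply_reg_gradient(sol$x, g, p) - rhs0)) / max(abs(rhs0)), 1e-8)

  # shifted SPD operator, direct residual verification with a weak preconditioner
  hop <- function(u) apply_reg_gradient(u, g, p) + 0.5 * u
  sol2 <- pcg(hop, rhs, function(r) r, tol = 1e-10, maxit = 200)
  expect_lt(max(abs(hop(sol2$x) - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("gauss_newton: degenerate input, objective decrease, and shift recovery", {
  g <- make_grid(c(16, 16, 16))
  co <- coords(g)
  p <- reg_params(1e-3, 1e-5)
  cfg <- solver_config(nt = 4, maxit = 10)
  m0 <- exp(-(sin((co[[1]] - pi) / 2)^2 + sin((co[[2]] - pi) / 2)^2 +
                sin((co[[3]] - pi) / 2)^2) * 8)

  # identical images: immediate convergence, v stays zero, degenerate residual
  fit0 <- gauss_newton(m0, m0, g, p, cfg)
  expect_true(fit0$converged)
  expect_equal(fit0$iterations, 0L)
  expect_equal(max(abs(fit0$v)), 0)
  expect_true(fit0$degenerate)
  expect_equal(fit0$r, 0)

  # recover a smooth deformation
  vtrue <- vector_field(g)
  vtrue[, , , 1] <- 0.4 * sin(co[[2]])
  vtrue[, , , 2] <- 0.2 * sin(co[[3]])
  m1 <- solve_state(m0, vtrue, g, time_grid(8), keep_all = FALSE)
  fit <- gauss_newton(m0, m1, g, p, cfg)
  expect_true(fit$converged)
  expect_lt(fit$r, 0.1)
  expect_true(all(diff(fit$objective) < 0)) # Armijo guarantees strict decrease
  expect_true(all(fit$jac_range > 0))

  # warm start at the optimum with unchanged parameters re-converges immediately
  fit2 <- gauss_newton(m0, m1, g, p, cfg, v_init = fit$v)
  expect_true(fit2$converged)
  expect_lte(fit2$iterations, 2L)
})

test_that("regularization monotonicity at the optimum", {
  g <- make_grid(c(16, 16, 16))
  co <- coords(g)
  cfg <- solver_config(nt = 4, maxit = 15, gtol = 2e-2)
  m0 <- exp(-(sin((co[[1]] - pi) / 2)^2 + sin((co[[2]] - pi) / 2)^2 +
                sin((co[[3]] - pi) / 2)^2) * 8)
  vtrue <- vector_field(g)
  vtrue[, , , 1] <- 0.5 * sin(co[[2]])
  vtrue[, , , 3] <- 0.3 * cos(co[[1]])
  m1 <- solve_state(m0, vtrue, g, time_grid(8), keep_all = FALSE)

  # increasing beta_w tenfold never increases |div v*|
  f1 <- gauss_newton(m0, m1, g, reg_params(1e-3, 1e-5), cfg)
  f2 <- gauss_newton(m0, m1, g, reg_params(1e-3, 1e-4), cfg)
  d1 <- velreg:::l2_norm(fd_divergence(f1$v, g), g)
  d2 <- velreg:::l2_norm(fd_divergence(f2$v, g), g)
  expect_lte(d2, d1 * (1 + 1e-3))

  # increasing beta_v tenfold never decreases the final mismatch
  f3 <- gauss_newton(m0, m1, g, reg_params(1e-2, 1e-5), cfg)
  mis1 <- 0.5 * sum((f1$m_final - m1)^2) * g$voxvol
  mis3 <- 0.5 * sum((f3$m_final - m1)^2) * g$voxvol
  expect_gte(mis3, mis1 * (1 - 1e-3))
})
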
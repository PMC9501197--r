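test_that("departure-point tracing: identity at v = 0, exact for constant velocity", {
  g <- make_grid(c(16, 16, 16))
  pts <- velreg:::grid_points(g)

  dep0 <- trace_departure_points(vector_field(g), g, 0.25)
  expect_equal(dep0$X, pts)
  expect_equal(max(abs(dep0$disp)), 0)

  v <- vector_field(g)
  v[, , , 1] <- 0.83
  dep <- trace_departure_points(v, g, 0.25, "linear")
  expect_lt(max(abs(dep$disp[, 1] + 0.25 * 0.83)), 1e-13)
  expect_equal(max(abs(dep$disp[, 2:3])), 0)
  expect_error(trace_departure_points(v, g, -1), "dt")
})

test_that("departure-point tracing is O(dt^3) per step on a rotation field", {
  # rigid rotation in the x1-x2 plane about the domain center
  g <- make_grid(c(24, 24, 12))
  co <- coords(g)
  om <- 0.8
  v <- vector_field(g)
  v[, , , 1] <- -om * (co[[2]] - pi) * exp(-((co[[1]] - pi)^2 + (co[[2]] - pi)^2) / 8)
  v[, , , 2] <- om * (co[[1]] - pi) * exp(-((co[[1]] - pi)^2 + (co[[2]] - pi)^2) / 8)
  # near the center the envelope is ~1 so characteristics rotate rigidly;
  # compare the traced point of the center-adjacent node against the exact
  # rotation, for two step sizes
  node <- which.min((velreg:::grid_points(g)[, 1] - (pi + pi / 6))^2 +
                      (velreg:::grid_points(g)[, 2] - pi)^2 +
                      (velreg:::grid_points(g)[, 3] - pi)^2)
  errs <- vapply(c(0.2, 0.1), function(dt) {
    dep <- trace_departure_points(v, g, dt, "cubic")
    x <- velreg:::grid_points(g)[node, ]
    rel <- x[1:2] - pi
    env <- exp(-sum(rel^2) / 8)
    ang <- -om * env * dt # backward rotation (approx: envelope ~const on circle)
    exact <- c(pi + cos(ang) * rel[1] - sin(ang) * rel[2],
               pi + sin(ang) * rel[1] + cos(ang) * rel[2], x[3])
    sqrt(sum((dep$X[node, ] - exact)^2))
  }, 0)
  expect_gt(log2(errs[1] / errs[2]), 2.2) # ~O(dt^3)
})

test_that("periodic interpolation is node-exact, reproduces linear data, and has the right orders", {
  g <- make_grid(c(16, 16, 16))
  co <- coords(g)
  f <- rand_smooth(g, 2, seed = 4)
  pts <- velreg:::grid_points(g)
  for (sch in c("linear", "cubic")) {
    expect_equal(interp_image(f, pts, g, sch), as.numeric(f), tolerance = 1e-14)
  }

  flin <- 0.3 + 0.7 * co[[1]] * 0 + 0.2 * sin(0 * co[[1]]) # constant reproduced
  mid <- sweep(pts, 2, c(g$h[1] / 2, 0, 0), "+")
  # a + b x1 is NOT periodic; use it only away from the wrap seam
  inner <- pts[, 1] < 2 * pi - g$h[1]
  flin2 <- 0.3 + 0.7 * co[[1]]
  vals <- interp_image(flin2, mid[inner, ], g, "linear")
  expect_lt(max(abs(vals - (0.3 + 0.7 * mid[inner, 1]))), 1e-12)

  # refinement slopes on sin(x1) with a 0.3 h offset
  errs <- sapply(c(16L, 32L), function(n) {
    gn <- make_grid(c(n, 8, 8))
    con <- coords(gn)
    fn <- sin(con[[1]])
    ptsn <- velreg:::grid_points(gn)
    off <- sweep(ptsn, 2, c(0.3 * gn$h[1], 0, 0), "+")
    c(
      max(abs(interp_image(fn, off, gn, "linear") - sin(off[, 1]))),
      max(abs(interp_image(fn, off, gn, "cubic") - sin(off[, 1])))
    )
  })
  expect_gt(log2(errs[1, 1] / errs[1, 2]), 1.7) # linear ~ O(h^2)
  expect_lt(log2(errs[1, 1] / errs[1, 2]), 2.3)
  expect_gt(log2(errs[2, 1] / errs[2, 2]), 3.6) # cubic ~ O(h^4)
  expect_lt(log2(errs[2, 1] / errs[2, 2]), 4.4)
})

test_that("state solve: bitwise identity at v = 0, analytic shift, maximum principle", {
  g <- make_grid(c(32, 32, 32))
  co <- coords(g)
  tg <- time_grid(4)
  m0 <- sin(co[[1]]) + 0.2 * cos(2 * co[[2]])

  slices <- solve_state(m0, vector_field(g), g, tg)
  expect_length(slices, 5)
  for (s in slices) expect_identical(as.numeric(s), as.numeric(m0))

  v <- vector_field(g)
  v[, , , 1] <- 0.7
  mf <- solve_state(m0, v, g, tg, "linear", keep_all = FALSE)
  exact <- sin(co[[1]] - 0.7) + 0.2 * cos(2 * co[[2]])
  expect_lt(max(abs(mf - exact)), 4 * max(g$h)^2) # O(h^2) interpolation

  # maximum principle for linear interpolation
  set.seed(10)
  v2 <- rand_smooth_vf(g, amp = 1)
  mf2 <- solve_state(m0, v2, g, tg, "linear", keep_all = FALSE)
  expect_gte(min(mf2), min(m0) - 1e-12)
  expect_lte(max(mf2), max(m0) + 1e-12)
})

test_that("advection is reversible under simultaneous space-time refinement", {
  roundtrip_err <- function(n, nt) {
    g <- make_grid(c(n, n, n))
    co <- coords(g)
    m0 <- sin(co[[1]]) * cos(2 * co[[2]]) + 0.3 * cos(co[[3]])
    v <- vector_field(g)
    v[, , , 1] <- 0.5 * sin(co[[2]])
    v[, , , 2] <- 0.4 * cos(co[[3]])
    v[, , , 3] <- 0.3 * sin(co[[1]])
    fwd <- solve_state(m0, v, g, time_grid(nt), "cubic", keep_all = FALSE)
    back <- solve_state(fwd, -v, g, time_grid(nt), "cubic", keep_all = FALSE)
    max(abs(back - m0)) / diff(range(m0))
  }
  e_coarse <- roundtrip_err(24, 4)
  e_fine <- roundtrip_err(48, 8)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_coarse, 0.05)
})

test_that("adjoint continuity solve conserves mass and reduces to advection", {
  g <- make_grid(c(32, 32, 32))
  co <- coords(g)
  fin <- 1 + 0.5 * sin(co[[1]]) * sin(co[[2]])
  tg <- time_grid(4)

  # v = 0: all slices equal the final condition bitwise
  slices <- solve_adjoint(fin, vector_field(g), g, tg)
  for (s in slices) expect_identical(as.numeric(s), as.numeric(fin))

  # constant velocity: lambda(.,0) is the final condition shifted by +c
  vc <- vector_field(g)
  vc[, , , 1] <- 0.7
  lam0 <- solve_adjoint(fin, vc, g, tg, "linear", keep_all = FALSE)
  expect_lt(max(abs(lam0 - (1 + 0.5 * sin(co[[1]] + 0.7) * sin(co[[2]])))),
            4 * max(g$h)^2)

  # mass conservation at O(dt^2): slope over nt refinement
  gm <- make_grid(c(64, 64, 12))
  cm <- coords(gm)
  v <- vector_field(gm)
  v[, , , 1] <- 2.5 * sin(cm[[2]]) * cos(cm[[1]])
  v[, , , 2] <- 2.0 * cos(cm[[1]]) * sin(cm[[2]])
  finm <- 1 + 0.5 * sin(cm[[1]]) * sin(cm[[2]])
  errs <- vapply(c(4L, 8L, 16L), function(nt) {
    lam <- solve_adjoint(finm, v, gm, time_grid(nt), "cubic", keep_all = FALSE)
    abs(sum(lam) - sum(finm)) / abs(sum(finm))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_gt(log2(errs[1] / errs[3]) / 2, 1.4) # ~O(dt^2) up to the spatial floor
})

test_that("incremental solve is the exact linearization and matches the v = 0 closed form", {
  g <- make_grid(c(32, 32, 32))
  tg <- time_grid(4)
  m0 <- rand_smooth(g, 2, seed = 20)
  v <- rand_smooth_vf(g, amp = 0.4, seed = 21)
  vt <- rand_smooth_vf(g, amp = 1, seed = 22)

  # vtilde = 0 -> 0
  inc0 <- solve_incremental(vector_field(g), v, m0, g, tg)
  expect_equal(max(abs(inc0$mtilde_final)), 0)
  expect_equal(max(abs(inc0$lambda_tilde[[tg$nt + 1]])), 0)

  # linearization: |m(v + eps vt)(1) - m(v)(1) - eps mtilde(1)| = O(eps^2)
  inc <- solve_incremental(vt, v, m0, g, tg)
  base <- solve_state(m0, v, g, tg, "cubic", keep_all = FALSE)
  errs <- vapply(c(1e-2, 1e-3), function(eps) {
    pert <- solve_state(m0, v + eps * vt, g, tg, "cubic", keep_all = FALSE)
    max(abs(pert - base - eps * inc$mtilde_final))
  }, 0)
  expect_gt(log10(errs[1] / errs[2]), 1.7) # quadratic in eps

  # v = 0: mtilde(1) = -vt . grad m0 (up to the interpolant-derivative stencil)
  incz <- solve_incremental(vt, vector_field(g), m0, g, tg)
  gm <- fd_gradient(m0, g)
  closed <- -(vt[, , , 1] * gm[, , , 1] + vt[, , , 2] * gm[, , , 2] +
                vt[, , , 3] * gm[, , , 3])
  expect_lt(max(abs(incz$mtilde_final - closed)) / max(abs(closed)), 0.05)
})

test_that("forward/adjoint transport duality holds to discretization order", {
  g <- make_grid(c(24, 24, 24))
  tg <- time_grid(6)
  m0 <- rand_smooth(g, 2, seed = 30)
  q <- rand_smooth(g, 2, seed = 31)
  v <- rand_smooth_vf(g, amp = 0.5, seed = 32)
  mf <- solve_state(m0, v, g, tg, "cubic", keep_all = FALSE)
  lam0 <- solve_adjoint(q, v, g, tg, "cubic", keep_all = FALSE)
  a <- l2i(mf, q, g)
  b <- l2i(m0, lam0, g)
  expect_lt(abs(a - b) / max(abs(a), abs(b)), 0.02)
})

test_that("deformation map: identity and translation give J = 1; divergence-free flows preserve volume", {
  g <- make_grid(c(24, 24, 24))
  tg <- time_grid(4)

  dm0 <- deformation_map(vector_field(g), g, tg)
  expect_equal(max(abs(dm0$u)), 0)
  expect_equal(dm0$jac_range, c(1, 1))

  vtr <- vector_field(g)
  vtr[, , , 1] <- 0.9; vtr[, , , 3] <- -0.4
  dmt <- deformation_map(vtr, g, tg)
  expect_lt(max(abs(dmt$u[, , , 1] + 0.9)), 1e-12)
  expect_lt(max(abs(dmt$jac - 1)), 1e-10)

  vdf <- divfree_vf(g, 0.8)
  errs <- vapply(c(2L, 4L, 8L), function(nt) {
    max(abs(deformation_map(vdf, g, time_grid(nt), "cubic")$jac - 1))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("CFL number follows the direct formula and halves when nt doubles", {
  g <- make_grid(c(64, 64, 64))
  expect_equal(cfl_number(vector_field(g), g, time_grid(4)), 0)
  v <- vector_field(g)
  v[, , , 2] <- 1
  expect_equal(cfl_number(v, g, time_grid(4)), 0.25 / (2 * pi / 64), tolerance = 1e-12)
  expect_equal(cfl_number(v, g, time_grid(8)), cfl_number(v, g, time_grid(4)) / 2)
})
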
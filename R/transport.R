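#' Semi-Lagrangian transport
#'
#' The hyperbolic PDEs of the registration problem (forward advection of the
#' template, backward continuity transport of the adjoint, and their
#' linearizations) are solved with an unconditionally stable semi-Lagrangian
#' scheme: departure points are traced with a 2nd-order Runge-Kutta step along
#' the (stationary) velocity and field values are picked up there by periodic
#' interpolation. Because the velocity is stationary, the departure points are
#' computed once per velocity and reused for every transport solve.
#'
#' @name transport
NULL

#' Time grid for the pseudo-time interval [0, 1]
#'
#' @param nt positive integer number of semi-Lagrangian steps; the solver
#'   stores \code{nt + 1} time slices at \eqn{t_j = j/nt}.
#' @return a list of class \code{time_grid} with \code{nt} and \code{dt}.
#' @export
time_grid <- function(nt) {
  nt <- as.integer(nt)
  if (is.na(nt) || nt < 1L) stop("nt must be a positive integer")
  structure(list(nt = nt, dt = 1 / nt), class = "time_grid")
}

interp_order <- function(scheme) {
  scheme <- match.arg(scheme, c("linear", "cubic"))
  if (scheme == "cubic") 3L else 1L
}

wrap_coords <- function(x) x %% (2 * pi)

#' Periodic interpolation of a scalar image at off-grid points
#'
#' Multilinear or cubic Lagrange interpolation with periodic wraparound. Both
#' schemes reproduce grid-node values exactly; linear is exact for trilinear
#' polynomials (O(h^2) for smooth fields), cubic Lagrange for tricubics
#' (O(h^4)).
#'
#' @param f scalar image on \code{grid}.
#' @param points an \code{M x 3} matrix of physical coordinates (radians; any
#'   values, wrapped internally).
#' @param grid the grid.
#' @param scheme \code{"linear"} or \code{"cubic"}.
#' @param derivative if TRUE, return the \code{M x 3} spatial derivative of
#'   the interpolant instead of its values.
#' @return numeric vector of length M (or an M x 3 matrix of derivatives).
#' @export
interp_image <- function(f, points, grid, scheme = "cubic", derivative = FALSE) {
  check_scalar(f, grid)
  pts <- wrap_coords(as.matrix(points))
  if (ncol(pts) != 3L) stop("points must be an M x 3 matrix")
  ord <- interp_order(scheme)
  if (ord == 3L && any(grid$dims < 4L)) stop("cubic interpolation needs >= 4 points per axis")
  if (derivative) {
    ip_gather_grad(as.numeric(f), pts, grid$dims, ord)
  } else {
    ip_gather(as.numeric(f), pts, grid$dims, ord)
  }
}

# Interpolate all three components of a vector field at points: M x 3 matrix.
interp_vf <- function(v, pts, grid, ord) {
  cbind(
    ip_gather(as.numeric(v[, , , 1]), pts, grid$dims, ord),
    ip_gather(as.numeric(v[, , , 2]), pts, grid$dims, ord),
    ip_gather(as.numeric(v[, , , 3]), pts, grid$dims, ord)
  )
}

#' Trace semi-Lagrangian departure points
#'
#' For every grid node x computes the RK2 (midpoint) backward characteristic
#' step \eqn{x^* = x - dt\, v(x)}, \eqn{X = x - (dt/2)(v(x) + v(x^*))}, with
#' \eqn{v(x^*)} obtained by periodic interpolation. Exact for constant
#' velocity fields; O(dt^3) local error per step otherwise.
#'
#' @param v vector field on \code{grid}.
#' @param grid the grid.
#' @param dt time-step length.
#' @param scheme interpolation scheme used for the velocity.
#' @return a list with \code{X} (wrapped departure coordinates, M x 3),
#'   \code{disp} (unwrapped displacement X - x), and \code{xstar} (wrapped
#'   Euler predictor points).
#' @export
trace_departure_points <- function(v, grid, dt, scheme = "cubic") {
  check_vector(v, grid)
  if (dt <= 0) stop("dt must be positive")
  ord <- interp_order(scheme)
  x0 <- grid_points(grid)
  vmat <- vf_as_matrix(v, grid)
  xstar <- wrap_coords(x0 - dt * vmat)
  vstar <- interp_vf(v, xstar, grid, ord)
  disp <- -(dt / 2) * (vmat + vstar)
  list(X = wrap_coords(x0 + disp), disp = disp, xstar = xstar)
}

# ---- shared per-velocity transport state -----------------------------------
# Departure points and the interpolated velocity Jacobian at the predictor
# points are computed once per velocity and shared by the state solve, the
# discrete gradient and every Hessian matvec.
sl_setup <- function(v, grid, tg, scheme) {
  check_vector(v, grid)
  ord <- interp_order(scheme)
  dep <- trace_departure_points(v, grid, tg$dt, scheme)
  # gradv_star[[b]][, a] = d v_a / d x_b at xstar (needed for the dX/dv chain)
  gv <- vector("list", 3)
  for (a in 1:3) {
    gv[[a]] <- ip_gather_grad(as.numeric(v[, , , a]), dep$xstar, grid$dims, ord)
  }
  list(
    v = v, grid = grid, tg = tg, scheme = scheme, ord = ord,
    X = dep$X, disp = dep$disp, xstar = dep$xstar, gradv_star = gv
  )
}

#' Solve the forward transport (state) equation
#'
#' Advects the template intensities forward in pseudo-time:
#' \eqn{\partial_t m + v\cdot\nabla m = 0}, \eqn{m(\cdot,0) = m_0}. One
#' semi-Lagrangian step is \eqn{m^{j+1}(x) = m^j(X)}.
#'
#' @param m0 template image.
#' @param v stationary velocity field.
#' @param grid the grid.
#' @param tg a \code{\link{time_grid}}.
#' @param scheme interpolation scheme.
#' @param keep_all if TRUE return all \code{nt + 1} slices, else only the
#'   final image.
#' @return a list of slices (\code{keep_all = TRUE}; slice 1 is \code{m0}
#'   itself) or the final 3D image.
#' @export
solve_state <- function(m0, v, grid, tg, scheme = "cubic", keep_all = TRUE) {
  check_scalar(m0, grid)
  prob <- sl_setup(v, grid, tg, scheme)
  sl_state(m0, prob, keep_all = keep_all)$slices_or_final
}

# internal: state solve on a prepared problem; also returns the interpolant
# derivative at the departure points per step (reused by jvp/vjp).
sl_state <- function(m0, prob, keep_all = TRUE, need_grad = FALSE) {
  grid <- prob$grid
  nt <- prob$tg$nt
  slices <- if (keep_all) vector("list", nt + 1) else NULL
  gradm <- if (need_grad) vector("list", nt) else NULL
  m <- m0
  if (keep_all) slices[[1]] <- m
  for (j in seq_len(nt)) {
    if (need_grad) {
      gradm[[j]] <- ip_gather_grad(as.numeric(m), prob$X, grid$dims, prob$ord)
    }
    m <- array(ip_gather(as.numeric(m), prob$X, grid$dims, prob$ord), dim = grid$dims)
    if (keep_all) slices[[j + 1]] <- m
  }
  list(
    slices_or_final = if (keep_all) slices else m,
    final = m, slices = slices, gradm = gradm
  )
}

#' Solve the adjoint (continuity) equation backward in time
#'
#' Transports the adjoint variable by the continuity equation
#' \eqn{-\partial_t \lambda - \nabla\cdot(\lambda v) = 0} backward from its
#' final condition at t = 1. One reversed-time semi-Lagrangian step traces the
#' characteristic forward (departure points of \eqn{-v}) and applies the
#' trapezoidal integrating factor of the source \eqn{-\lambda \nabla\cdot v}:
#' \deqn{\lambda^{j+1}(x) = \lambda^j(X)\,\exp\big((dt/2)[\nabla\cdot v(x) +
#'   \nabla\cdot v(X)]\big),}
#' with \eqn{\nabla\cdot v} from \code{\link{fd_divergence}}. The scheme
#' conserves \eqn{\int \lambda\,dx} to O(dt^2) on the periodic domain; for
#' divergence-free v it reduces to pure advection.
#'
#' @param final the final condition \eqn{\lambda(\cdot, 1)}.
#' @inheritParams solve_state
#' @return list of slices ordered backward in time: slice 1 is \code{final}
#'   (t = 1), slice \code{nt + 1} is \eqn{\lambda(\cdot, 0)}; or the t = 0
#'   image if \code{keep_all = FALSE}.
#' @export
solve_adjoint <- function(final, v, grid, tg, scheme = "cubic", keep_all = TRUE) {
  check_scalar(final, grid)
  check_vector(v, grid)
  ord <- interp_order(scheme)
  dep <- trace_departure_points(-v, grid, tg$dt, scheme)
  divv <- fd_divergence(v, grid)
  divv_dep <- ip_gather(as.numeric(divv), dep$X, grid$dims, ord)
  fac <- exp((tg$dt / 2) * (as.numeric(divv) + divv_dep))
  lam <- final
  slices <- if (keep_all) vector("list", tg$nt + 1) else NULL
  if (keep_all) slices[[1]] <- lam
  for (j in seq_len(tg$nt)) {
    lam <- array(ip_gather(as.numeric(lam), dep$X, grid$dims, ord) * fac,
                 dim = grid$dims)
    if (keep_all) slices[[j + 1]] <- lam
  }
  if (keep_all) slices else lam
}

# ---- exact discrete linearization ------------------------------------------
# The objective is differentiated discretize-then-optimize style: the
# directional derivative (jvp) and its exact transpose (vjp) differentiate the
# semi-Lagrangian stepping INCLUDING the dependence of the departure points on
# the velocity,
#   dX[u] = -(dt/2) (u(x) + u(x*) - dt (grad v)(x*) u(x)),
# so gradient and Gauss-Newton Hessian agree with finite differences of the
# discrete objective to rounding.

# dX/dv applied to a perturbation u: returns M x 3 matrix.
sl_dX <- function(u, prob) {
  grid <- prob$grid
  dt <- prob$tg$dt
  umat <- vf_as_matrix(u, grid)
  ustar <- interp_vf(u, prob$xstar, grid, prob$ord)
  gvu <- cbind(
    rowSums(prob$gradv_star[[1]] * umat),
    rowSums(prob$gradv_star[[2]] * umat),
    rowSums(prob$gradv_star[[3]] * umat)
  )
  -(dt / 2) * (umat + ustar - dt * gvu)
}

# Transpose of sl_dX applied to an M x 3 field q: returns a vector field.
sl_dX_transpose <- function(q, prob) {
  grid <- prob$grid
  dt <- prob$tg$dt
  qs <- cbind(
    ip_scatter(q[, 1], prob$xstar, grid$dims, prob$ord),
    ip_scatter(q[, 2], prob$xstar, grid$dims, prob$ord),
    ip_scatter(q[, 3], prob$xstar, grid$dims, prob$ord)
  )
  gvq <- cbind(
    prob$gradv_star[[1]][, 1] * q[, 1] + prob$gradv_star[[2]][, 1] * q[, 2] +
      prob$gradv_star[[3]][, 1] * q[, 3],
    prob$gradv_star[[1]][, 2] * q[, 1] + prob$gradv_star[[2]][, 2] * q[, 2] +
      prob$gradv_star[[3]][, 2] * q[, 3],
    prob$gradv_star[[1]][, 3] * q[, 1] + prob$gradv_star[[2]][, 3] * q[, 2] +
      prob$gradv_star[[3]][, 3] * q[, 3]
  )
  vf_from_matrix(-(dt / 2) * (q + qs - dt * gvq), grid)
}

# Forward mode: mtilde(1) = d m(1)/dv . u  (exact for the discrete scheme).
sl_state_jvp <- function(u, prob, state) {
  grid <- prob$grid
  dX <- sl_dX(u, prob)
  mt <- numeric(grid$n)
  for (j in seq_len(prob$tg$nt)) {
    mt <- ip_gather(mt, prob$X, grid$dims, prob$ord) +
      rowSums(state$gradm[[j]] * dX)
  }
  array(mt, dim = grid$dims)
}

# Reverse mode: (d m(1)/dv)^T z. Optionally returns the backward-transported
# multiplier slices (the discrete incremental adjoint trajectory).
sl_state_vjp <- function(z, prob, state, keep_lambda = FALSE) {
  grid <- prob$grid
  nt <- prob$tg$nt
  lam <- as.numeric(z)
  gX <- matrix(0, nrow = grid$n, ncol = 3)
  lam_slices <- if (keep_lambda) vector("list", nt + 1) else NULL
  if (keep_lambda) lam_slices[[1]] <- array(lam, dim = grid$dims)
  for (j in rev(seq_len(nt))) {
    gX <- gX + lam * state$gradm[[j]]
    lam <- ip_scatter(lam, prob$X, grid$dims, prob$ord)
    if (keep_lambda) lam_slices[[nt + 2 - j]] <- array(lam, dim = grid$dims)
  }
  list(grad = sl_dX_transpose(gX, prob), lambda0 = array(lam, dim = grid$dims),
       lam_slices = lam_slices)
}

#' Incremental (Gauss-Newton) transport pair
#'
#' Solves the linearized state equation forward
#' (\eqn{\partial_t \tilde m + v\cdot\nabla\tilde m + \tilde v\cdot\nabla m =
#' 0}, \eqn{\tilde m(\cdot,0)=0}) as the exact directional derivative of the
#' discrete semi-Lagrangian state solve, and then transports
#' \eqn{\tilde\lambda(\cdot,1) = -\tilde m(\cdot,1)} backward with the exact
#' discrete transpose of the advection steps. Both are consistent
#' discretizations of the incremental transport/continuity pair.
#'
#' @param vtilde perturbation velocity field.
#' @param v base velocity field.
#' @param m0 template image (the trajectory is recomputed internally from it).
#' @inheritParams solve_state
#' @return list with \code{mtilde_final} (\eqn{\tilde m(\cdot,1)}) and
#'   \code{lambda_tilde} (backward multiplier slices, slice 1 at t = 1).
#' @export
solve_incremental <- function(vtilde, v, m0, grid, tg, scheme = "cubic") {
  check_vector(vtilde, grid)
  prob <- sl_setup(v, grid, tg, scheme)
  state <- sl_state(m0, prob, keep_all = FALSE, need_grad = TRUE)
  mt <- sl_state_jvp(vtilde, prob, state)
  back <- sl_state_vjp(-mt, prob, state, keep_lambda = TRUE)
  list(mtilde_final = mt, lambda_tilde = back$lam_slices)
}

#' Deformation map, deformation gradient and Jacobian determinant
#'
#' Composes the \code{nt} semi-Lagrangian backward departure steps over
#' \eqn{[0,1]} into the map \eqn{y(x) = x + u(x)} with \eqn{m(x,1) =
#' m_0(y(x))}; the displacement is accumulated by interpolation so it stays
#' smooth across the periodic wrap. The deformation gradient is
#' \eqn{F = I + \nabla u} (8th-order periodic FD) and \eqn{J = \det F}.
#'
#' @inheritParams solve_state
#' @return list with \code{u} (displacement vector field), \code{jac}
#'   (Jacobian-determinant image) and \code{jac_range} (its min and max).
#' @export
deformation_map <- function(v, grid, tg, scheme = "cubic") {
  prob <- sl_setup(v, grid, tg, scheme)
  u <- matrix(0, nrow = grid$n, ncol = 3)
  for (j in seq_len(prob$tg$nt)) {
    u <- cbind(
      ip_gather(u[, 1], prob$X, grid$dims, prob$ord),
      ip_gather(u[, 2], prob$X, grid$dims, prob$ord),
      ip_gather(u[, 3], prob$X, grid$dims, prob$ord)
    ) + prob$disp
  }
  uf <- vf_from_matrix(u, grid)
  # F = I + grad u, row a holds the gradient of displacement component a
  gu <- vector("list", 3)
  for (a in 1:3) gu[[a]] <- fd_gradient(uf[, , , a], grid)
  f11 <- 1 + gu[[1]][, , , 1]; f12 <- gu[[1]][, , , 2]; f13 <- gu[[1]][, , , 3]
  f21 <- gu[[2]][, , , 1]; f22 <- 1 + gu[[2]][, , , 2]; f23 <- gu[[2]][, , , 3]
  f31 <- gu[[3]][, , , 1]; f32 <- gu[[3]][, , , 2]; f33 <- 1 + gu[[3]][, , , 3]
  jac <- f11 * (f22 * f33 - f23 * f32) -
    f12 * (f21 * f33 - f23 * f31) +
    f13 * (f21 * f32 - f22 * f31)
  list(u = uf, jac = jac, jac_range = range(jac))
}

#' CFL number of a velocity / time-grid combination
#'
#' Maximum displacement per semi-Lagrangian step in voxel units:
#' \eqn{\max_i \max_x |v_i(x)|\, dt / h_i}. The scheme is unconditionally
#' stable, but large CFL numbers degrade the accuracy of the characteristic
#' tracing.
#'
#' @inheritParams solve_state
#' @return a nonnegative scalar.
#' @export
cfl_number <- function(v, grid, tg) {
  check_vector(v, grid)
  max(vapply(1:3, function(a) max(abs(v[, , , a])) * tg$dt / grid$h[a], 0))
}
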
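#' Solver configuration
#'
#' @param gtol relative gradient tolerance: the Gauss-Newton iteration stops
#'   once \eqn{\|g_k\|/\|g_0\| \le} \code{gtol}.
#' @param maxit maximum number of Gauss-Newton iterations.
#' @param krylov_maxit maximum inner PCG iterations per Newton step.
#' @param c1 Armijo sufficient-decrease constant.
#' @param ls_backtrack backtracking factor of the line search.
#' @param ls_maxtrials maximum line-search trials before giving up.
#' @param scheme interpolation scheme of the semi-Lagrangian solver
#'   (\code{"linear"} or \code{"cubic"}).
#' @param nt number of semi-Lagrangian time steps.
#' @param verbose print per-iteration diagnostics.
#' @return a list of class \code{solver_config}.
#' @export
solver_config <- function(gtol = 5e-2, maxit = 50L, krylov_maxit = 50L,
                          c1 = 1e-4, ls_backtrack = 0.5, ls_maxtrials = 20L,
                          scheme = "cubic", nt = 4L, verbose = FALSE) {
  if (gtol <= 0 || gtol >= 1) stop("gtol must lie in (0, 1)")
  if (maxit < 1 || krylov_maxit < 1 || ls_maxtrials < 1) {
    stop("iteration counts must be positive")
  }
  scheme <- match.arg(scheme, c("linear", "cubic"))
  structure(list(
    gtol = gtol, maxit = as.integer(maxit),
    krylov_maxit = as.integer(krylov_maxit), c1 = c1,
    ls_backtrack = ls_backtrack, ls_maxtrials = as.integer(ls_maxtrials),
    scheme = scheme, nt = as.integer(nt), verbose = isTRUE(verbose)
  ), class = "solver_config")
}

#' Registration objective
#'
#' \deqn{J(v) = \tfrac12 \int (m(\cdot,1) - m_1)^2 dx
#'   + \tfrac{\beta_v}{2}\langle -\Delta v, v\rangle
#'   + \tfrac{\beta_w}{2}\langle (I-\Delta)(\nabla\cdot v), \nabla\cdot v\rangle}
#' with \eqn{m(\cdot,1)} from the semi-Lagrangian state solve; integrals are
#' voxel sums times the voxel volume.
#'
#' @param v velocity field.
#' @param m0,m1 template and reference images on \code{grid}.
#' @param grid the grid.
#' @param p \code{\link{reg_params}}.
#' @param cfg \code{\link{solver_config}}.
#' @return list with \code{total}, \code{mismatch}, \code{reg_v}, \code{reg_w}
#'   and the deformed template \code{m_final}.
#' @export
objective <- function(v, m0, m1, grid, p, cfg = solver_config()) {
  check_scalar(m0, grid); check_scalar(m1, grid)
  mf <- solve_state(m0, v, grid, time_grid(cfg$nt), cfg$scheme, keep_all = FALSE)
  obj_parts(v, mf, m1, grid, p)
}

obj_parts <- function(v, m_final, m1, grid, p) {
  mismatch <- 0.5 * sum((m_final - m1)^2) * grid$voxvol
  en <- spec_reg_energies(vf_as_matrix(v, grid), grid$dims)
  rv <- 0.5 * p$beta_v * en[1] * grid$voxvol
  rw <- 0.5 * p$beta_w * en[2] * grid$voxvol
  list(total = mismatch + rv + rw, mismatch = mismatch, reg_v = rv, reg_w = rw,
       m_final = m_final)
}

#' Reduced gradient of the registration objective
#'
#' \eqn{g = \beta_v A v + \beta_w \nabla^*(I-\Delta)\nabla\cdot v + b}, where
#' the body force \eqn{b} is the derivative of the mismatch with respect to
#' the velocity. By default (\code{method = "discrete"}) \eqn{b} is the exact
#' discrete adjoint of the semi-Lagrangian state solve (reverse-mode
#' differentiation including the departure-point chain), so the gradient
#' matches central finite differences of the objective to rounding.
#' \code{method = "continuity"} instead evaluates the continuous-adjoint
#' formula \eqn{b = \int_0^1 \lambda \nabla m\, dt} with \eqn{\lambda} from
#' \code{\link{solve_adjoint}} (final condition \eqn{m_1 - m(\cdot,1)}),
#' \eqn{\nabla m} from \code{\link{fd_gradient}} and trapezoidal quadrature;
#' the two agree to the discretization order O(dt^2 + h^p).
#'
#' @inheritParams objective
#' @param method \code{"discrete"} (default) or \code{"continuity"}.
#' @return the gradient vector field (ascent direction of the objective).
#' @export
reduced_gradient <- function(v, m0, m1, grid, p, cfg = solver_config(),
                             method = c("discrete", "continuity")) {
  method <- match.arg(method)
  tg <- time_grid(cfg$nt)
  if (method == "discrete") {
    prob <- sl_setup(v, grid, tg, cfg$scheme)
    state <- sl_state(m0, prob, keep_all = FALSE, need_grad = TRUE)
    b <- sl_state_vjp(state$final - m1, prob, state)$grad
  } else {
    slices <- solve_state(m0, v, grid, tg, cfg$scheme, keep_all = TRUE)
    lam <- solve_adjoint(m1 - slices[[tg$nt + 1]], v, grid, tg, cfg$scheme)
    # b = integral lambda grad m dt with lambda(1) = m1 - m(.,1), which makes
    # g the ascent direction of the objective (checked against the central
    # finite-difference oracle); trapezoidal rule over the stored slices,
    # lambda slices run backward in time.
    b <- array(0, dim = c(grid$dims, 3))
    for (j in 0:tg$nt) {
      wt <- if (j == 0 || j == tg$nt) 0.5 else 1
      b <- b + wt * tg$dt * fd_gradient(slices[[j + 1]], grid) *
        as.numeric(lam[[tg$nt + 1 - j]])
    }
  }
  apply_reg_gradient(v, grid, p) + b
}

#' Gauss-Newton Hessian matvec
#'
#' Applies the Gauss-Newton approximation of the reduced-space Hessian,
#' \eqn{H\tilde v = \beta_v A \tilde v + \beta_w \nabla^*(I-\Delta)\nabla\cdot
#' \tilde v + J_m^T J_m \tilde v}, where \eqn{J_m = dm(\cdot,1)/dv} is applied
#' by forward-mode and its transpose by reverse-mode differentiation of the
#' discrete transport solve, making the operator symmetric positive
#' semidefinite to rounding.
#'
#' @param vtilde the field the Hessian is applied to.
#' @inheritParams objective
#' @return the vector field \eqn{H\tilde v}.
#' @export
hessian_matvec <- function(vtilde, v, m0, m1, grid, p, cfg = solver_config()) {
  prob <- sl_setup(v, grid, time_grid(cfg$nt), cfg$scheme)
  state <- sl_state(m0, prob, keep_all = FALSE, need_grad = TRUE)
  hessian_matvec_cached(vtilde, prob, state, p)
}

hessian_matvec_cached <- function(vtilde, prob, state, p) {
  mt <- sl_state_jvp(vtilde, prob, state)
  apply_reg_gradient(vtilde, prob$grid, p) + sl_state_vjp(mt, prob, state)$grad
}

#' Matrix-free preconditioned conjugate gradients
#'
#' Standard PCG for \eqn{H x = b} with a symmetric positive semidefinite
#' operator; iteration stops when the residual drops below \code{tol * |b|} or
#' on detected negative curvature (then the current iterate is returned; if
#' negative curvature appears in the first iteration the preconditioned
#' steepest-descent direction is returned instead).
#'
#' @param apply_h function taking and returning a field (the operator).
#' @param rhs right-hand side field.
#' @param apply_precond function applying the preconditioner inverse.
#' @param tol relative residual tolerance.
#' @param maxit maximum iterations.
#' @return list with \code{x}, \code{iterations}, \code{relres},
#'   \code{neg_curvature}.
#' @export
pcg <- function(apply_h, rhs, apply_precond, tol = 1e-2, maxit = 50L) {
  bnorm <- sqrt(sum(rhs^2))
  x <- array(0, dim = dim(rhs))
  if (bnorm == 0) {
    return(list(x = x, iterations = 0L, relres = 0, neg_curvature = FALSE))
  }
  r <- rhs
  z <- apply_precond(r)
  pdir <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    hp <- apply_h(pdir)
    php <- sum(pdir * hp)
    if (php <= 0) {
      if (it == 1L) x <- z
      return(list(x = x, iterations = it - 1L,
                  relres = sqrt(sum(r^2)) / bnorm, neg_curvature = TRUE))
    }
    alpha <- rz / php
    x <- x + alpha * pdir
    r <- r - alpha * hp
    rnorm <- sqrt(sum(r^2))
    if (rnorm <= tol * bnorm) {
      return(list(x = x, iterations = it, relres = rnorm / bnorm,
                  neg_curvature = FALSE))
    }
    z <- apply_precond(r)
    rz_new <- sum(r * z)
    pdir <- z + (rz_new / rz) * pdir
    rz <- rz_new
  }
  list(x = x, iterations = maxit, relres = sqrt(sum(r^2)) / bnorm,
       neg_curvature = FALSE)
}

#' Reduced-space Gauss-Newton-Krylov registration solver
#'
#' Minimizes the registration objective over stationary velocity fields:
#' outer Gauss-Newton iterations, inner matrix-free PCG solves of
#' \eqn{H\tilde v = -g} preconditioned with the exact spectral inverse of the
#' regularization operator, globalized with an Armijo backtracking line
#' search. The inner (Krylov) tolerance follows the superlinear forcing rule
#' \eqn{\eta_k = \min(0.5, \sqrt{\|g_k\|/\|g_0\|})}.
#'
#' @inheritParams objective
#' @param v_init optional warm-start velocity (default: zero field).
#' @return an object of class \code{registration_fit}: the velocity
#'   \code{v}, objective/gradient histories, relative residual \code{r},
#'   Jacobian-determinant range, iteration count and convergence flag.
#' @examples
#' g <- make_grid(c(16, 16, 16))
#' co <- grid_coord_arrays(g)
#' m0 <- exp(-(sin(co[[1]] / 2 - pi / 2)^2 + sin(co[[2]] / 2 - pi / 2)^2 +
#'   sin(co[[3]] / 2 - pi / 2)^2) * 8)
#' v <- vector_field(g)
#' v[, , , 1] <- 0.4 * sin(co[[2]])
#' m1 <- solve_state(m0, v, g, time_grid(4), keep_all = FALSE)
#' fit <- gauss_newton(m0, m1, g, reg_params(1e-3, 1e-5),
#'   solver_config(nt = 4, maxit = 10))
#' fit$r
#' @export
gauss_newton <- function(m0, m1, grid, p, cfg = solver_config(), v_init = NULL) {
  stopifnot(inherits(p, "reg_params"), inherits(cfg, "solver_config"))
  check_scalar(m0, grid, "template"); check_scalar(m1, grid, "reference")
  tg <- time_grid(cfg$nt)
  v <- if (is.null(v_init)) vector_field(grid) else {
    check_vector(v_init, grid); v_init
  }
  pre_mismatch <- 0.5 * sum((m0 - m1)^2) * grid$voxvol
  obj_hist <- numeric(0)
  gnorm_hist <- numeric(0)
  # Convergence is measured against the problem-scale reference gradient at
  # zero velocity (beta-independent since the regularizer vanishes there).
  # For a cold start this is the usual |g_k|/|g_0| criterion; for warm starts
  # it keeps the tolerance meaningful when the initial gradient is already
  # small.
  g0norm <- if (is.null(v_init)) {
    NA_real_ # set from the first iterate below
  } else {
    prob0 <- sl_setup(vector_field(grid), grid, tg, cfg$scheme)
    state0 <- sl_state(m0, prob0, keep_all = FALSE, need_grad = TRUE)
    l2_norm(sl_state_vjp(state0$final - m1, prob0, state0)$grad, grid)
  }
  converged <- FALSE
  degenerate <- pre_mismatch == 0
  m_final <- m0
  iters <- 0L

  for (k in seq_len(cfg$maxit + 1L)) {
    prob <- sl_setup(v, grid, tg, cfg$scheme)
    state <- sl_state(m0, prob, keep_all = FALSE, need_grad = TRUE)
    m_final <- state$final
    parts <- obj_parts(v, m_final, m1, grid, p)
    if (!is.finite(parts$total)) stop("objective is not finite; aborting")
    g <- apply_reg_gradient(v, grid, p) +
      sl_state_vjp(m_final - m1, prob, state)$grad
    gnorm <- l2_norm(g, grid)
    obj_hist <- c(obj_hist, parts$total)
    gnorm_hist <- c(gnorm_hist, gnorm)
    if (k == 1L && is.na(g0norm)) g0norm <- gnorm
    if (cfg$verbose) {
      message(sprintf("GN %2d: J = %.6e (mis %.3e) |g|/|g0| = %.3e",
                      k - 1L, parts$total, parts$mismatch,
                      if (g0norm > 0) gnorm / g0norm else 0))
    }
    tol_met <- g0norm == 0 || gnorm <= cfg$gtol * g0norm
    # a warm start with (possibly) changed regularization takes at least one
    # step so that the returned iterate reflects the current problem
    if (tol_met && (g0norm == 0 || k > 1L || is.null(v_init))) {
      converged <- TRUE
      break
    }
    if (k > cfg$maxit) break
    eta <- min(0.5, sqrt(gnorm / g0norm))
    sol <- pcg(
      function(u) hessian_matvec_cached(u, prob, state, p),
      -g,
      function(r) invert_reg_operator(r, grid, p),
      tol = eta, maxit = cfg$krylov_maxit
    )
    vt <- sol$x
    slope <- l2_inner(g, vt, grid)
    if (slope >= 0) { # not a descent direction; fall back
      vt <- -invert_reg_operator(g, grid, p)
      slope <- l2_inner(g, vt, grid)
    }
    alpha <- 1
    accepted <- FALSE
    for (ls in seq_len(cfg$ls_maxtrials)) {
      trial <- v + alpha * vt
      ob <- objective(trial, m0, m1, grid, p, cfg)
      if (is.finite(ob$total) &&
          ob$total <= parts$total + cfg$c1 * alpha * slope) {
        v <- trial
        accepted <- TRUE
        break
      }
      alpha <- alpha * cfg$ls_backtrack
    }
    iters <- iters + 1L
    if (!accepted) {
      # line search exhausted: converged if the iterate already met the
      # tolerance (warm start at an optimum), otherwise flag not-converged
      converged <- tol_met
      break
    }
  }

  dm <- deformation_map(v, grid, tg, cfg$scheme)
  final_mismatch <- 0.5 * sum((m_final - m1)^2) * grid$voxvol
  r <- if (degenerate) 0 else final_mismatch / pre_mismatch
  structure(list(
    v = v, m_final = m_final, objective = obj_hist, gradnorm = gnorm_hist,
    r = r, degenerate = degenerate, jac_range = dm$jac_range,
    jac = dm$jac, iterations = iters, converged = converged,
    params = p, config = cfg, grid = grid
  ), class = "registration_fit")
}

#' @export
print.registration_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<registration_fit> %s after %d Gauss-Newton iterations\n",
           "  relative residual r = %.4g, J in [%.4g, %.4g]\n",
           "  beta_v = %.3g, beta_w = %.3g, |g|/|g0| = %.3g\n"),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$r, x$jac_range[1], x$jac_range[2],
    x$params$beta_v, x$params$beta_w,
    if (length(x$gradnorm) && x$gradnorm[1] > 0) {
      tail(x$gradnorm, 1) / x$gradnorm[1]
    } else 0
  ))
  invisible(x)
}
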
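#' Jacobian-determinant admissibility bounds
#'
#' A velocity is admissible when the Jacobian determinant of its deformation
#' map satisfies \eqn{J_{min} \le \min J} and \eqn{\max J \le 1/J_{min}}.
#' Tight bounds (jmin close to 1) force simple deformations; loose bounds
#' admit complex, nearly non-diffeomorphic ones.
#'
#' @param jmin lower bound, in (0, 1). Default 0.25.
#' @return list of class \code{jac_bounds} with \code{jmin} and \code{jmax}.
#' @export
jac_bounds <- function(jmin = 0.25) {
  if (!is.numeric(jmin) || length(jmin) != 1 || jmin <= 0 || jmin >= 1) {
    stop("jmin must lie in (0, 1)")
  }
  structure(list(jmin = jmin, jmax = 1 / jmin), class = "jac_bounds")
}

is_admissible <- function(jac_range, bounds) {
  jac_range[1] >= bounds$jmin && jac_range[2] <= bounds$jmax
}

BETA_V_INIT <- 1
BETA_V_MIN <- 1e-5
BETA_W_INIT <- 1e-5
BETA_W_MIN <- 1e-7

new_trace <- function() {
  data.frame(
    phase = character(0), beta_v = numeric(0), beta_w = numeric(0),
    jac_min = numeric(0), jac_max = numeric(0), residual = numeric(0),
    admissible = logical(0), iterations = integer(0)
  )
}

add_trial <- function(trace, phase, fit) {
  rbind(trace, data.frame(
    phase = phase, beta_v = fit$params$beta_v, beta_w = fit$params$beta_w,
    jac_min = fit$jac_range[1], jac_max = fit$jac_range[2], residual = fit$r,
    admissible = NA, iterations = fit$iterations
  ))
}

#' Stage 1 of the regularization-parameter search: beta_v
#'
#' With \code{beta_w} fixed at its initial value 1e-5, solves the registration
#' starting from \code{beta_v = 1} (under-fitting) and reduces \code{beta_v}
#' by one order of magnitude per trial (warm-starting each solve from the
#' previous velocity) until the Jacobian bounds are breached or the floor
#' 1e-5 is reached. On a breach, a binary search (geometric midpoints, i.e.
#' bisection in log10) probes between the last admissible and first
#' inadmissible value and terminates when the relative change falls below 10%
#' of the previous valid \code{beta_v}. Returns the last admissible value.
#'
#' @param m0,m1 template and reference images.
#' @param grid the grid.
#' @param bounds \code{\link{jac_bounds}}.
#' @param cfg \code{\link{solver_config}} used for the inner solves.
#' @param beta_w_fixed divergence weight held fixed during this stage.
#' @return list with \code{beta_v} (NA on failure), \code{success},
#'   \code{trace} (one row per trial), and \code{v} (velocity of the last
#'   admissible solve, for warm starts).
#' @export
search_beta_v <- function(m0, m1, grid, bounds = jac_bounds(),
                          cfg = solver_config(), beta_w_fixed = BETA_W_INIT) {
  trace <- new_trace()
  v_warm <- NULL
  solve_at <- function(bv, phase) {
    fit <- gauss_newton(m0, m1, grid, reg_params(bv, beta_w_fixed), cfg,
                        v_init = v_warm)
    row <- add_trial(trace, phase, fit)
    row$admissible[nrow(row)] <- is_admissible(fit$jac_range, bounds)
    trace <<- row
    v_warm <<- fit$v
    list(fit = fit, admissible = row$admissible[nrow(row)])
  }

  bv <- BETA_V_INIT
  last_good <- NA_real_
  first_bad <- NA_real_
  fit_good <- NULL
  repeat {
    res <- solve_at(bv, "decade")
    if (res$admissible) {
      last_good <- bv
      fit_good <- res$fit
      if (bv <= BETA_V_MIN * (1 + 1e-9)) {
        return(list(beta_v = BETA_V_MIN, success = TRUE, trace = trace,
                    v = fit_good$v, fit = fit_good))
      }
      bv <- bv / 10
      if (bv < BETA_V_MIN) bv <- BETA_V_MIN
    } else {
      first_bad <- bv
      break
    }
  }
  if (is.na(last_good)) {
    warning("beta_v search failed: the initial trial (beta_v = 1) already violates the Jacobian bounds")
    return(list(beta_v = NA_real_, success = FALSE, trace = trace, v = NULL))
  }
  # binary search in log10 between the bracketing values
  lo <- log10(first_bad)
  hi <- log10(last_good)
  repeat {
    mid <- 10^((lo + hi) / 2)
    if (abs(mid - last_good) / last_good < 0.1) break
    res <- solve_at(mid, "binary")
    if (res$admissible) {
      last_good <- mid
      fit_good <- res$fit
      hi <- log10(mid)
    } else {
      lo <- log10(mid)
    }
  }
  list(beta_v = last_good, success = TRUE, trace = trace, v = fit_good$v,
       fit = fit_good)
}

#' Stage 2 of the regularization-parameter search: beta_w
#'
#' Fixes \code{beta_v} at the stage-1 result and reduces \code{beta_w} from
#' 1e-5 by one order of magnitude per trial (warm starts) until the Jacobian
#' bounds are violated or the floor 1e-7 is reached; the last admissible value
#' is returned.
#'
#' @inheritParams search_beta_v
#' @param beta_v_star the stage-1 result.
#' @param v_warm warm-start velocity (typically the stage-1 solution).
#' @return list like \code{\link{search_beta_v}} with \code{beta_w}.
#' @export
search_beta_w <- function(m0, m1, grid, beta_v_star, bounds = jac_bounds(),
                          cfg = solver_config(), v_warm = NULL) {
  trace <- new_trace()
  last_good <- NA_real_
  fit_good <- NULL
  bw <- BETA_W_INIT
  repeat {
    fit <- gauss_newton(m0, m1, grid, reg_params(beta_v_star, bw), cfg,
                        v_init = v_warm)
    adm <- is_admissible(fit$jac_range, bounds)
    trace <- add_trial(trace, "w-decade", fit)
    trace$admissible[nrow(trace)] <- adm
    v_warm <- fit$v
    if (!adm) break
    last_good <- bw
    fit_good <- fit
    if (bw <= BETA_W_MIN * (1 + 1e-9)) break
    bw <- bw / 10
    if (bw < BETA_W_MIN) bw <- BETA_W_MIN
  }
  if (is.na(last_good)) {
    warning("beta_w search failed: beta_w = 1e-5 already violates the Jacobian bounds at beta_v*")
    return(list(beta_w = NA_real_, success = FALSE, trace = trace, v = NULL,
                fit = NULL))
  }
  list(beta_w = last_good, success = TRUE, trace = trace, v = fit_good$v,
       fit = fit_good)
}

#' Two-stage automatic regularization-parameter search
#'
#' Composition of \code{\link{search_beta_v}} and \code{\link{search_beta_w}}:
#' selects the smallest regularization weights whose registration keeps the
#' Jacobian determinant within the prescribed bounds. The returned parameters
#' always satisfy \eqn{\beta_v^* \in [10^{-5}, 1]} and
#' \eqn{\beta_w^* \in [10^{-7}, 10^{-5}]}.
#'
#' @inheritParams search_beta_v
#' @return list with \code{params} (\code{\link{reg_params}}), \code{trace}
#'   (all trials, stages concatenated), \code{fit} (a final registration at
#'   the selected parameters, warm-started), and \code{success}.
#' @export
parameter_search <- function(m0, m1, grid, bounds = jac_bounds(),
                             cfg = solver_config()) {
  s1 <- search_beta_v(m0, m1, grid, bounds, cfg)
  if (!s1$success) {
    return(list(params = NULL, trace = s1$trace, fit = NULL, success = FALSE))
  }
  s2 <- search_beta_w(m0, m1, grid, s1$beta_v, bounds, cfg, v_warm = s1$v)
  trace <- rbind(s1$trace, s2$trace)
  if (!s2$success) {
    # stage 1 already observed an admissible solve at beta_w = 1e-5; if the
    # stage-2 re-check flips within solver tolerance, keep that last valid
    # configuration rather than failing the search
    return(list(params = reg_params(s1$beta_v, BETA_W_INIT), trace = trace,
                fit = s1$fit, success = TRUE, bw_fallback = TRUE))
  }
  list(params = reg_params(s1$beta_v, s2$beta_w), trace = trace,
       fit = s2$fit, success = TRUE, bw_fallback = FALSE)
}

#' Regularization-parameter continuation
#'
#' Replays the search ladder towards known target parameters without
#' admissibility checks or binary search: stage 1 solves at
#' \eqn{\beta_v \in \{1, 0.1, \dots, 10^{\lceil \log_{10}\beta_v^*\rceil}\}}
#' and then at \eqn{\beta_v^*} with \eqn{\beta_w} fixed at 1e-5, warm-starting
#' each solve; stage 2 fixes \eqn{\beta_v^*} and reduces \eqn{\beta_w} by
#' decades down to \eqn{\beta_w^*}. Much cheaper than the search; intended for
#' cohorts where the parameters were identified on one image pair.
#'
#' @inheritParams search_beta_v
#' @param target \code{\link{reg_params}} from a previous search.
#' @return the final \code{registration_fit} with the continuation ladder in
#'   \code{$ladder}.
#' @export
parameter_continuation <- function(m0, m1, grid, target, cfg = solver_config()) {
  stopifnot(inherits(target, "reg_params"))
  bv_ladder <- 10^(seq(0, ceiling(log10(target$beta_v)), by = -1))
  if (utils::tail(bv_ladder, 1) > target$beta_v * (1 + 1e-12)) {
    bv_ladder <- c(bv_ladder, target$beta_v)
  }
  bw_ladder <- 10^(seq(log10(BETA_W_INIT), ceiling(log10(target$beta_w)), by = -1))
  if (utils::tail(bw_ladder, 1) > target$beta_w * (1 + 1e-12)) {
    bw_ladder <- c(bw_ladder, target$beta_w)
  }
  v <- NULL
  ladder <- data.frame(beta_v = numeric(0), beta_w = numeric(0),
                       residual = numeric(0), iterations = integer(0))
  fit <- NULL
  for (bv in bv_ladder) {
    fit <- gauss_newton(m0, m1, grid, reg_params(bv, BETA_W_INIT), cfg, v_init = v)
    v <- fit$v
    ladder <- rbind(ladder, data.frame(beta_v = bv, beta_w = BETA_W_INIT,
                                       residual = fit$r,
                                       iterations = fit$iterations))
  }
  for (bw in bw_ladder[-1]) {
    fit <- gauss_newton(m0, m1, grid, reg_params(target$beta_v, bw), cfg, v_init = v)
    v <- fit$v
    ladder <- rbind(ladder, data.frame(beta_v = target$beta_v, beta_w = bw,
                                       residual = fit$r,
                                       iterations = fit$iterations))
  }
  fit$ladder <- ladder
  fit
}

#' Resolution-dependent choice of interpolation order and time steps
#'
#' Up to 256 points per axis: cubic interpolation with \code{nt = 4} (or
#' linear with \code{nt = 8} when \code{prefer = "linear"}). Beyond that:
#' linear interpolation with \code{nt} growing proportionally to the largest
#' dimension so the CFL number stays fixed as resolution doubles.
#'
#' @param grid the grid.
#' @param prefer preferred scheme at moderate resolution, \code{"cubic"}
#'   (default) or \code{"linear"}.
#' @return list with \code{scheme} and \code{nt}.
#' @export
choose_discretization <- function(grid, prefer = c("cubic", "linear")) {
  prefer <- match.arg(prefer)
  maxdim <- max(grid$dims)
  if (maxdim <= 256) {
    if (prefer == "cubic") list(scheme = "cubic", nt = 4L)
    else list(scheme = "linear", nt = 8L)
  } else {
    list(scheme = "linear", nt = 8L * as.integer(ceiling(maxdim / 256)))
  }
}
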
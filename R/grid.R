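#' Periodic grid on \eqn{\Omega = [0, 2\pi)^3}
#'
#' The solver works on the normalized periodic domain \eqn{[0,2\pi)^3}
#' discretized with a regular, node-centered grid: node \code{(i,j,k)}
#' (0-based) sits at \eqn{(2\pi i/N_1, 2\pi j/N_2, 2\pi k/N_3)}. All spatial
#' operators in the package (finite differences, spectral regularization,
#' interpolation) wrap periodically on this grid.
#'
#' @param dims integer vector of length 3, grid points per axis. Each entry
#'   must be even and at least 4 (the 8th-order stencils additionally require
#'   at least 9 points per axis, checked where they are used).
#' @return an object of class \code{velreg_grid} with elements \code{dims},
#'   \code{h} (spacing \eqn{2\pi/N_i}), \code{n} (total voxel count) and
#'   \code{voxvol} (voxel volume \eqn{\prod h_i}).
#' @examples
#' g <- make_grid(c(16, 16, 16))
#' g$h
#' @export
make_grid <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || anyNA(dims)) {
    stop("`dims` must be an integer vector of length 3")
  }
  if (any(dims < 4L) || any(dims %% 2L != 0L)) {
    stop("grid dimensions must be even and >= 4")
  }
  g <- list(
    dims = dims,
    h = 2 * pi / dims,
    n = prod(dims),
    voxvol = prod(2 * pi / dims),
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "velreg_grid"
  g
}

#' @export
print.velreg_grid <- function(x, ...) {
  cat(sprintf(
    "<velreg_grid> %d x %d x %d on [0,2pi)^3, h = (%.4g, %.4g, %.4g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$h[1], x$h[2], x$h[3]
  ))
  invisible(x)
}

is_grid <- function(x) inherits(x, "velreg_grid")

#' Node coordinates of a grid
#'
#' @param grid a \code{\link{make_grid}} object.
#' @return a list with per-axis coordinate vectors (\code{axes}) and, lazily
#'   cached, an \code{n x 3} matrix of all node coordinates (\code{points}).
#' @keywords internal
grid_axes <- function(grid) {
  lapply(1:3, function(a) (seq_len(grid$dims[a]) - 1) * grid$h[a])
}

grid_points <- function(grid) {
  if (!is.null(grid$cache$points)) return(grid$cache$points)
  ax <- grid_axes(grid)
  d <- grid$dims
  pts <- cbind(
    rep(ax[[1]], times = d[2] * d[3]),
    rep(rep(ax[[2]], each = d[1]), times = d[3]),
    rep(ax[[3]], each = d[1] * d[2])
  )
  grid$cache$points <- pts
  pts
}

# Full 3D coordinate arrays (each dims-shaped).
grid_coord_arrays <- function(grid) {
  pts <- grid_points(grid)
  lapply(1:3, function(a) array(pts[, a], dim = grid$dims))
}

# Integer frequency indices of the periodic Fourier basis, FFT storage order:
# 0, 1, ..., N/2, -(N/2 - 1), ..., -1 for even N.
axis_freq <- function(n) {
  half <- n %/% 2
  c(0:half, seq_len(n - half - 1) - (n - half))
}

# Frequencies used for first-derivative-like factors: the (ambiguous-sign)
# Nyquist mode of an even axis is set to zero.
axis_freq_deriv <- function(n) {
  k <- axis_freq(n)
  if (n %% 2 == 0) k[n %/% 2 + 1] <- 0
  k
}

# Cached spectral multiplier arrays: k2 = |k|^2 (full, for the Laplacian) and
# kd1..kd3 (derivative convention) per axis.
grid_spectra <- function(grid) {
  if (!is.null(grid$cache$spectra)) return(grid$cache$spectra)
  d <- grid$dims
  k1 <- axis_freq(d[1]); k2 <- axis_freq(d[2]); k3 <- axis_freq(d[3])
  ksq <- array(0, dim = d)
  ksq <- ksq + array(k1^2, dim = d)
  ksq <- ksq + array(rep(k2^2, each = d[1]), dim = d)
  ksq <- ksq + array(rep(k3^2, each = d[1] * d[2]), dim = d)
  kd <- list(
    array(axis_freq_deriv(d[1]), dim = d),
    array(rep(axis_freq_deriv(d[2]), each = d[1]), dim = d),
    array(rep(axis_freq_deriv(d[3]), each = d[1] * d[2]), dim = d)
  )
  sp <- list(ksq = ksq, kd = kd, kd_sq = kd[[1]]^2 + kd[[2]]^2 + kd[[3]]^2)
  grid$cache$spectra <- sp
  sp
}

fftn <- function(x) stats::fft(x)
ifftn_real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

#' Scalar and vector fields
#'
#' Scalar images are plain 3D arrays whose dimensions match the grid; vector
#' fields (velocities, body forces, displacements) are 4D arrays with
#' dimensions \code{c(grid$dims, 3)}, component order (x1, x2, x3), units
#' radians per unit pseudo-time. These constructors validate shape and
#' finiteness.
#'
#' @param grid a \code{\link{make_grid}} object.
#' @param values for \code{scalar_field}, a numeric vector or 3D array with
#'   \code{grid$n} entries; for \code{vector_field}, a numeric vector/array
#'   with \code{3 * grid$n} entries (defaults to the zero field).
#' @return a 3D (scalar) or 4D (vector) numeric array.
#' @export
scalar_field <- function(grid, values = 0) {
  stopifnot(is_grid(grid))
  if (length(values) == 1L) values <- rep(as.numeric(values), grid$n)
  if (length(values) != grid$n) stop("scalar field has wrong length for grid")
  check_finite(values, "scalar field")
  array(as.numeric(values), dim = grid$dims)
}

#' @rdname scalar_field
#' @export
vector_field <- function(grid, values = 0) {
  stopifnot(is_grid(grid))
  if (length(values) == 1L) values <- rep(as.numeric(values), 3 * grid$n)
  if (length(values) != 3 * grid$n) stop("vector field has wrong length for grid")
  check_finite(values, "vector field")
  array(as.numeric(values), dim = c(grid$dims, 3))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  invisible(TRUE)
}

check_scalar <- function(f, grid, what = "image") {
  if (!identical(dim(f)[1:3], grid$dims) || length(f) != grid$n) {
    stop(sprintf("%s does not match the grid dimensions", what))
  }
  check_finite(f, what)
}

check_vector <- function(v, grid, what = "vector field") {
  if (length(v) != 3 * grid$n ||
      !identical(dim(v), c(grid$dims, 3L)) && !identical(dim(v), c(grid$dims, 3))) {
    stop(sprintf("%s does not match the grid dimensions", what))
  }
  check_finite(v, what)
}

# n x 3 matrix view of a vector field (no copy of semantics, R copies anyway).
vf_as_matrix <- function(v, grid) matrix(v, nrow = grid$n, ncol = 3)
vf_from_matrix <- function(m, grid) array(m, dim = c(grid$dims, 3))

#' Discrete L2 inner product \eqn{\langle a, b\rangle = \sum a b \prod h_i}
#' @keywords internal
l2_inner <- function(a, b, grid) sum(a * b) * grid$voxvol

l2_norm <- function(a, grid) sqrt(sum(a * a) * grid$voxvol)
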
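#' Spatial differential and regularization operators
#'
#' First-order derivatives along the solver path use a centered 8th-order
#' periodic finite-difference stencil (weights 4/5, -1/5, 4/105, -1/280 at
#' offsets 1..4). The regularization operators act spectrally: the velocity
#' penalty is the H1 seminorm (vector Laplacian), the divergence penalty the
#' full H1 norm of \eqn{w = \nabla\cdot v}.
#'
#' @name operators
NULL

# Circularly shift an array along one axis by s (positive = forward index).
shift_axis <- function(x, axis, s) {
  d <- dim(x)
  n <- d[axis]
  idx <- ((seq_len(n) - 1 + s) %% n) + 1
  switch(axis,
    x[idx, , , drop = FALSE],
    x[, idx, , drop = FALSE],
    x[, , idx, drop = FALSE]
  )
}

fd8_weights <- c(4 / 5, -1 / 5, 4 / 105, -1 / 280)

# d/dx_axis with the centered 8th-order periodic stencil.
fd_partial <- function(f, grid, axis) {
  out <- array(0, dim = grid$dims)
  for (s in 1:4) {
    out <- out + fd8_weights[s] * (shift_axis(f, axis, s) - shift_axis(f, axis, -s))
  }
  out / grid$h[axis]
}

#' 8th-order periodic finite-difference gradient
#'
#' @param f scalar image (3D array on \code{grid}).
#' @param grid a \code{\link{make_grid}} object with at least 9 points per axis.
#' @return a vector field (4D array), component i holding \eqn{\partial f /
#'   \partial x_i}.
#' @export
fd_gradient <- function(f, grid) {
  check_scalar(f, grid)
  if (any(grid$dims < 9L)) stop("8th-order stencil needs >= 9 points per axis")
  out <- array(0, dim = c(grid$dims, 3))
  for (a in 1:3) out[, , , a] <- fd_partial(f, grid, a)
  out
}

#' 8th-order periodic finite-difference divergence
#'
#' @param u vector field (4D array on \code{grid}).
#' @inheritParams fd_gradient
#' @return scalar image \eqn{\nabla\cdot u}.
#' @export
fd_divergence <- function(u, grid) {
  check_vector(u, grid)
  if (any(grid$dims < 9L)) stop("8th-order stencil needs >= 9 points per axis")
  fd_partial(u[, , , 1], grid, 1) +
    fd_partial(u[, , , 2], grid, 2) +
    fd_partial(u[, , , 3], grid, 3)
}

#' Regularization parameters
#'
#' \code{beta_v} weights the H1-seminorm of the velocity, \code{beta_w} the H1
#' norm of its divergence \eqn{w = \nabla\cdot v}; larger \code{beta_w} pushes
#' the solution towards incompressibility.
#'
#' @param beta_v positive velocity regularization weight.
#' @param beta_w nonnegative divergence regularization weight.
#' @return a list of class \code{reg_params}.
#' @export
reg_params <- function(beta_v, beta_w = 0) {
  if (!is.numeric(beta_v) || length(beta_v) != 1 || beta_v <= 0) {
    stop("beta_v must be a positive scalar")
  }
  if (!is.numeric(beta_w) || length(beta_w) != 1 || beta_w < 0) {
    stop("beta_w must be a nonnegative scalar")
  }
  structure(list(beta_v = beta_v, beta_w = beta_w), class = "reg_params")
}

#' First variation of the combined regularizer
#'
#' Applies, spectrally, the operator obtained from the Lagrangian after
#' eliminating \eqn{w} and its multiplier:
#' \deqn{r(v) = \beta_v (-\Delta) v + \beta_w \nabla^*\big((I-\Delta)(\nabla\cdot v)\big),}
#' i.e. per Fourier mode the symmetric positive semidefinite matrix
#' \eqn{\beta_v |k|^2 I + \beta_w (1+|k|^2) k k^T}. The zero-frequency
#' (constant translation) mode is unpenalized and maps to zero; the Nyquist
#' mode of an even axis is treated as zero in the first-derivative factor
#' \eqn{kk^T}.
#'
#' @param v vector field.
#' @param grid grid the field lives on.
#' @param p a \code{\link{reg_params}} object.
#' @return the vector field \eqn{r(v)}.
#' @export
apply_reg_gradient <- function(v, grid, p) {
  check_vector(v, grid)
  stopifnot(inherits(p, "reg_params"))
  vf_from_matrix(spec_reg_apply(vf_as_matrix(v, grid), grid$dims,
                                p$beta_v, p$beta_w), grid)
}

#' Exact spectral inverse of the regularization operator
#'
#' Per Fourier mode inverts \eqn{\beta_v |k|^2 I + \beta_w (1+|k|^2) k k^T}
#' by the rank-one (Sherman-Morrison) update; the zero mode passes through
#' unchanged so constant translations remain controllable by the data term.
#' Used as the preconditioner of the Krylov solver.
#'
#' @inheritParams apply_reg_gradient
#' @param b vector field (right-hand side).
#' @return the vector field \eqn{r^{-1}(b)} (zero mode: identity).
#' @export
invert_reg_operator <- function(b, grid, p) {
  check_vector(b, grid)
  stopifnot(inherits(p, "reg_params"))
  vf_from_matrix(spec_reg_invert(vf_as_matrix(b, grid), grid$dims,
                                 p$beta_v, p$beta_w), grid)
}

# ---- grid transfer ---------------------------------------------------------

# Zero-pad a complex spectrum along one axis from Nc to Nf rows, splitting the
# Nyquist coefficient of an even source axis between +Nc/2 and -(Nc/2) so that
# real fields stay real and band-limited fields are reproduced exactly.
pad_spectrum_axis <- function(sp, axis, nf) {
  d <- dim(sp)
  nc <- d[axis]
  if (nf == nc) return(sp)
  if (nf < nc) stop("target axis smaller than source in spectral prolongation")
  dout <- d
  dout[axis] <- nf
  out <- array(complex(real = 0, imaginary = 0), dim = dout)
  ix_src <- function(i) switch(axis, sp[i, , , drop = FALSE],
                               sp[, i, , drop = FALSE], sp[, , i, drop = FALSE])
  assign_rows <- function(arr, i, val) {
    switch(axis,
      arr[i, , ] <- val,
      arr[, i, ] <- val,
      arr[, , i] <- val
    )
    arr
  }
  half <- nc %/% 2
  # non-negative frequencies 0 .. half-1 (even nc) or 0 .. half (odd nc)
  pos_hi <- if (nc %% 2 == 0) half - 1 else half
  out <- assign_rows(out, 1:(pos_hi + 1), ix_src(1:(pos_hi + 1)))
  # negative frequencies
  nneg <- nc - pos_hi - 1 - (nc %% 2 == 0) # count excluding Nyquist
  if (nc %% 2 == 0) {
    nyq <- ix_src(half + 1)
    out <- assign_rows(out, half + 1, nyq / 2)
    out <- assign_rows(out, nf - half + 1, nyq / 2)
    if (half + 2 <= nc) {
      out <- assign_rows(out, (nf - nc + half + 2):nf, ix_src((half + 2):nc))
    }
  } else {
    out <- assign_rows(out, (nf - nc + half + 2):nf, ix_src((half + 2):nc))
  }
  out
}

# Inverse of pad_spectrum_axis: truncate, summing the two fine half-Nyquist
# rows back into the coarse Nyquist row.
truncate_spectrum_axis <- function(sp, axis, nc) {
  d <- dim(sp)
  nf <- d[axis]
  if (nf == nc) return(sp)
  if (nf < nc) stop("target axis larger than source in spectral restriction")
  dout <- d
  dout[axis] <- nc
  out <- array(complex(real = 0, imaginary = 0), dim = dout)
  ix_src <- function(i) switch(axis, sp[i, , , drop = FALSE],
                               sp[, i, , drop = FALSE], sp[, , i, drop = FALSE])
  assign_rows <- function(arr, i, val) {
    switch(axis,
      arr[i, , ] <- val,
      arr[, i, ] <- val,
      arr[, , i] <- val
    )
    arr
  }
  half <- nc %/% 2
  pos_hi <- if (nc %% 2 == 0) half - 1 else half
  out <- assign_rows(out, 1:(pos_hi + 1), ix_src(1:(pos_hi + 1)))
  if (nc %% 2 == 0) {
    nyq <- ix_src(half + 1) + ix_src(nf - half + 1)
    out <- assign_rows(out, half + 1, nyq)
    if (half + 2 <= nc) {
      out <- assign_rows(out, (half + 2):nc, ix_src((nf - nc + half + 2):nf))
    }
  } else {
    out <- assign_rows(out, (half + 2):nc, ix_src((nf - nc + half + 2):nf))
  }
  out
}

#' Spectral prolongation (upsampling by Fourier zero-padding)
#'
#' Zero-pads the spectrum to the fine grid and inverse-transforms. Band-limited
#' fields are reproduced exactly at coincident points and the mean value is
#' conserved exactly. Works on scalar images and on vector fields
#' (componentwise); velocities keep their physical units so no rescaling is
#' needed after prolongation.
#'
#' @param f scalar image or vector field on \code{grid}.
#' @param grid source grid.
#' @param fine target grid with per-axis dimensions >= the source.
#' @return the field resampled on \code{fine}.
#' @export
spectral_prolong <- function(f, grid, fine) {
  stopifnot(is_grid(grid), is_grid(fine))
  if (any(fine$dims < grid$dims)) stop("fine grid must be at least as large as the source")
  scale <- fine$n / grid$n
  resample1 <- function(x) {
    sp <- fftn(x)
    for (a in 1:3) sp <- pad_spectrum_axis(sp, a, fine$dims[a])
    ifftn_real(sp) * scale
  }
  if (length(f) == grid$n) {
    check_scalar(f, grid)
    resample1(f)
  } else {
    check_vector(f, grid)
    out <- array(0, dim = c(fine$dims, 3))
    for (a in 1:3) out[, , , a] <- resample1(f[, , , a])
    out
  }
}

#' Spectral restriction (truncation of the Fourier spectrum)
#'
#' The adjoint-style inverse of \code{\link{spectral_prolong}}:
#' \code{spectral_restrict(spectral_prolong(f))} reproduces \code{f} exactly.
#'
#' @inheritParams spectral_prolong
#' @param coarse target grid with per-axis dimensions <= the source.
#' @export
spectral_restrict <- function(f, grid, coarse) {
  stopifnot(is_grid(grid), is_grid(coarse))
  if (any(coarse$dims > grid$dims)) stop("coarse grid must be at most as large as the source")
  scale <- coarse$n / grid$n
  resample1 <- function(x) {
    sp <- fftn(x)
    for (a in 1:3) sp <- truncate_spectrum_axis(sp, a, coarse$dims[a])
    ifftn_real(sp) * scale
  }
  if (length(f) == grid$n) {
    resample1(f)
  } else {
    out <- array(0, dim = c(coarse$dims, 3))
    for (a in 1:3) out[, , , a] <- resample1(f[, , , a])
    out
  }
}

#' Nearest-neighbor downsampling (decimation)
#'
#' Keeps every \code{factor}-th sample starting at index 0 along each axis,
#' the scheme used to produce the coarse-resolution inputs of the
#' multi-resolution experiments. Label maps stay integer-valued and the output
#' value set is a subset of the input's.
#'
#' @param f 3D array (image or integer label map).
#' @param factor positive integer dividing every dimension.
#' @return the decimated array.
#' @export
downsample_nn <- function(f, factor) {
  factor <- as.integer(factor)
  d <- dim(f)
  if (length(d) != 3L) stop("downsample_nn expects a 3D array")
  if (factor < 1L) stop("factor must be a positive integer")
  if (any(d %% factor != 0L)) stop("factor must divide every grid dimension")
  if (factor == 1L) return(f)
  idx <- lapply(d, function(n) seq(1, n, by = factor))
  f[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
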
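#' Synthetic registration benchmark
#'
#' Generates template/reference pairs with exactly known ground truth: the
#' template is a sum of ten indicator "blobs" whose radii are modulated by the
#' magnitude of a high-frequency spherical harmonic, the reference is the
#' template advected by an analytic multi-frequency velocity field, and the
#' discrete intensity levels define label maps for Dice evaluation.
#'
#' @name synthetic
NULL

#' Magnitude of a spherical harmonic
#'
#' \eqn{|Y_l^m(\theta,\phi)| = \big|\sqrt{\tfrac{2l+1}{4\pi}
#' \tfrac{(l-m)!}{(l+m)!}}\, P_l^m(\cos\phi)\big|}; the azimuthal factor
#' \eqn{e^{im\theta}} has unit modulus, so the magnitude depends only on the
#' polar angle (the \eqn{\theta} argument is accepted for interface symmetry
#' with the phase-shifted blob construction).
#'
#' @param theta azimuth (radians); does not affect the magnitude.
#' @param phi polar angle (radians); any values, enters through
#'   \eqn{\cos\phi}.
#' @param l degree, \code{l >= m}.
#' @param m order, nonnegative.
#' @return vector of magnitudes, recycled over \code{phi}.
#' @examples
#' sph_harm_magnitude(0, 1.2, 0, 0) # constant harmonic 1/sqrt(4 pi)
#' @export
sph_harm_magnitude <- function(theta, phi, l, m) {
  if (m > l || m < 0) stop("order m must satisfy 0 <= m <= l")
  norm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
  x <- cos(phi)
  # pracma::legendre returns rows m = 0..l (Condon-Shortley phase; the
  # magnitude is unaffected)
  p <- pracma::legendre(l, x)
  plm <- if (is.matrix(p)) p[m + 1, ] else p[m + 1]
  abs(norm * plm)
}

#' Specification of the spherical-harmonics template
#'
#' Ten indicator blobs: blob i covers \eqn{\|x - \hat x_i\|_2 \le
#' s\,|Y_l^m(\theta + \hat\theta_i, \phi + \hat\phi_i)|} where
#' \eqn{(\theta,\phi)} are the azimuth/polar angles of \eqn{x - \hat x_i},
#' offsets \eqn{\hat x_i} are uniform in \eqn{[-0.4\pi, 0.4\pi]^3} and the
#' angle shifts are random integer multiples of \eqn{\pi/2}. The radius scale
#' \eqn{s} (default 4) sets the blob size relative to the domain; with the
#' default, the foreground covers roughly a quarter of the volume and the
#' overlap depth (image intensity) typically reaches 6-7, giving several
#' labels with strongly decaying volume fractions.
#'
#' @param count number of blobs.
#' @param l,m spherical-harmonic degree and order.
#' @param radius_scale multiplier on the harmonic magnitude.
#' @param min_labels minimum number of distinct nonzero intensity levels the
#'   generated template must contain; generation retries with incremented
#'   seeds (up to \code{max_retries}) and fails otherwise.
#' @param max_retries retry cap.
#' @param seed integer seed controlling offsets and angle shifts.
#' @return list of class \code{blob_spec}.
#' @export
blob_spec <- function(count = 10L, l = 8L, m = 6L, radius_scale = 4,
                      min_labels = 4L, max_retries = 10L, seed = 1L) {
  if (m > l) stop("order m must not exceed degree l")
  structure(list(count = as.integer(count), l = as.integer(l),
                 m = as.integer(m), radius_scale = radius_scale,
                 min_labels = as.integer(min_labels),
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)), class = "blob_spec")
}

draw_blobs <- function(spec, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(
    offsets = matrix(stats::runif(3 * spec$count, -0.4 * pi, 0.4 * pi),
                     ncol = 3, byrow = TRUE),
    theta_shift = sample(0:3, spec$count, replace = TRUE) * pi / 2,
    phi_shift = sample(0:3, spec$count, replace = TRUE) * pi / 2
  )
}

#' Generate the spherical-harmonics template image and its labels
#'
#' Image coordinates are \eqn{(-\pi, \pi]^3} (the grid's \eqn{[0,2\pi)}
#' coordinates shifted by half the domain). The image value at a voxel is the
#' number of blobs covering it, an integer in \code{0..count}; label i marks
#' the voxels with intensity exactly i, for the intensity levels actually
#' present.
#'
#' @param grid the grid.
#' @param spec a \code{\link{blob_spec}}.
#' @return list with \code{image} (3D integer-valued array), \code{labels}
#'   (same array, interpreted as a label map with 0 = background),
#'   \code{label_values} (sorted nonzero intensities present) and
#'   \code{blobs} (the realized offsets/shifts).
#' @export
make_template <- function(grid, spec = blob_spec()) {
  stopifnot(is_grid(grid), inherits(spec, "blob_spec"))
  co <- grid_coord_arrays(grid)
  # map [0, 2pi) -> (-pi, pi]
  for (a in 1:3) co[[a]] <- ifelse(co[[a]] > pi, co[[a]] - 2 * pi, co[[a]])
  norm <- sqrt((2 * spec$l + 1) / (4 * pi) *
                 factorial(spec$l - spec$m) / factorial(spec$l + spec$m))
  for (attempt in 0:spec$max_retries) {
    blobs <- draw_blobs(spec, spec$seed + attempt)
    img <- array(0L, dim = grid$dims)
    for (i in seq_len(spec$count)) {
      dx <- co[[1]] - blobs$offsets[i, 1]
      dy <- co[[2]] - blobs$offsets[i, 2]
      dz <- co[[3]] - blobs$offsets[i, 3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      cospolar <- ifelse(r > 0, dz / pmax(r, .Machine$double.xmin), 1)
      polar <- acos(pmin(pmax(cospolar, -1), 1))
      pl <- pracma::legendre(spec$l, cos(polar + blobs$phi_shift[i]))
      plm <- if (is.matrix(pl)) pl[spec$m + 1, ] else pl
      radius <- spec$radius_scale * abs(norm * plm)
      img <- img + (r <= radius)
    }
    present <- sort(setdiff(unique(as.integer(img)), 0L))
    if (length(present) >= spec$min_labels) {
      return(list(image = array(as.numeric(img), dim = grid$dims),
                  labels = array(as.integer(img), dim = grid$dims),
                  label_values = present, blobs = blobs, seed_used = spec$seed + attempt))
    }
  }
  stop(sprintf("template generation produced fewer than %d labels after %d retries",
               spec$min_labels, spec$max_retries))
}

#' Analytic multi-frequency benchmark velocity
#'
#' \deqn{v_x = \sum_{k=1}^K k^{-1/2}\cos(ky)\cos(kx),\quad
#'   v_y = \sum_{k=1}^K k^{-1/2}\sin(kz)\sin(ky),\quad
#'   v_z = \sum_{k=1}^K k^{-1/2}\cos(kx)\cos(kz).}
#' Larger frequency caps K produce rougher velocity fields that are harder to
#' recover from coarse-resolution images.
#'
#' @param grid the grid.
#' @param K integer frequency cap (0 gives the zero field).
#' @return a vector field.
#' @export
make_velocity <- function(grid, K = 4L) {
  stopifnot(is_grid(grid))
  K <- as.integer(K)
  if (K < 0) stop("K must be nonnegative")
  if (K >= min(grid$dims) / 2) stop("K must be below the grid Nyquist limit")
  co <- grid_coord_arrays(grid)
  x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
  v <- vector_field(grid)
  for (k in seq_len(K)) {
    a <- k^-0.5
    v[, , , 1] <- v[, , , 1] + a * cos(k * y) * cos(k * x)
    v[, , , 2] <- v[, , , 2] + a * sin(k * z) * sin(k * y)
    v[, , , 3] <- v[, , , 3] + a * cos(k * x) * cos(k * z)
  }
  v
}

#' Generate a synthetic registration pair with ground truth
#'
#' The reference is the template advected over unit pseudo-time by the
#' analytic velocity (semi-Lagrangian solve; linear interpolation so the
#' transported intensities obey the maximum principle); reference labels are
#' produced by transporting each label indicator and thresholding at 0.5.
#'
#' @param grid the grid.
#' @param K velocity frequency cap (one of 4, 8, 12, 16 in the benchmark;
#'   0 gives an identical pair).
#' @param seed seed for the template randomness.
#' @param nt time steps used for generation (finer than the solver default
#'   for accuracy).
#' @param spec optional \code{\link{blob_spec}} overriding \code{seed}.
#' @return list with \code{m0}, \code{m1}, \code{labels0}, \code{labels1},
#'   \code{v_true}, \code{label_values}, \code{grid}.
#' @export
make_pair <- function(grid, K = 4L, seed = 1L, nt = 32L, spec = NULL) {
  if (is.null(spec)) spec <- blob_spec(seed = seed)
  tpl <- make_template(grid, spec)
  v <- make_velocity(grid, K)
  tg <- time_grid(nt)
  if (K == 0L) {
    m1 <- tpl$image
    labels1 <- tpl$labels
  } else {
    m1 <- solve_state(tpl$image, v, grid, tg, scheme = "linear", keep_all = FALSE)
    labels1 <- deform_labels(tpl$labels, v, grid, tg)
  }
  list(m0 = tpl$image, m1 = m1, labels0 = tpl$labels, labels1 = labels1,
       v_true = v, label_values = tpl$label_values, grid = grid,
       spec = tpl$blobs, seed = spec$seed)
}
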
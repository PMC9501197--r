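#' Registration quality metrics
#'
#' Dice overlap of label maps (plain, volume-weighted and
#' inverse-volume-weighted averages), the relative residual of the image
#' mismatch, and Jacobian-determinant statistics.
#'
#' @name metrics
NULL

#' Dice score of two voxel sets
#'
#' \eqn{D = 2|a\cap b| / (|a| + |b|)}; defined as 1 when both sets are empty
#' and 0 when exactly one is.
#'
#' @param a,b logical arrays (masks) of identical shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Per-label Dice report
#'
#' For every label in the shared vocabulary computes the Dice score and the
#' three averages: plain mean \eqn{D_a}, volume-weighted
#' \eqn{D_{vw} = \sum |l_1^i| D_i / \sum |l_1^i|} and inverse-volume-weighted
#' \eqn{D_{ivw} = \sum D_i/|l_1^i| / \sum 1/|l_1^i|} (weights from the
#' reference map). Labels empty in the reference are kept in \eqn{D_a} (their
#' Dice is 0 unless also empty in \code{l0}) but excluded from the weighted
#' averages, with a warning.
#'
#' @param l0,l1 integer label maps (0 = background) of identical shape.
#' @param labels optional integer vector fixing the label vocabulary (useful
#'   to score pre- and post-registration maps over the same set); default is
#'   the union of nonzero labels present in either map.
#' @return list of class \code{dice_report}: \code{per_label} data.frame
#'   (label, size0, size1, volume fraction alpha, dice) and \code{Da},
#'   \code{Dvw}, \code{Divw}.
#' @export
dice_report <- function(l0, l1, labels = NULL) {
  if (!identical(dim(l0), dim(l1))) stop("label maps must share a grid")
  labs <- if (is.null(labels)) {
    sort(setdiff(union(unique(as.integer(l0)), unique(as.integer(l1))), 0L))
  } else {
    sort(setdiff(as.integer(labels), 0L))
  }
  if (length(labs) == 0) stop("no nonzero labels present")
  d <- vapply(labs, function(v) dice(l0 == v, l1 == v), 0)
  n0 <- vapply(labs, function(v) sum(l0 == v), 0)
  n1 <- vapply(labs, function(v) sum(l1 == v), 0)
  nonempty <- n1 > 0
  if (any(!nonempty)) {
    warning(sprintf("labels empty in the reference map excluded from weighted averages: %s",
                    paste(labs[!nonempty], collapse = ", ")))
  }
  per_label <- data.frame(
    label = labs, size0 = n0, size1 = n1,
    alpha = n1 / sum(n1), dice = d
  )
  structure(list(
    per_label = per_label,
    Da = mean(d),
    Dvw = sum(n1[nonempty] * d[nonempty]) / sum(n1[nonempty]),
    Divw = sum(d[nonempty] / n1[nonempty]) / sum(1 / n1[nonempty])
  ), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> %d labels: Da = %.4f, Dvw = %.4f, Divw = %.4f\n",
              nrow(x$per_label), x$Da, x$Dvw, x$Divw))
  invisible(x)
}

#' Relative residual of the registration
#'
#' \eqn{r = \|m_{final} - m_1\|_2^2 / \|m_0 - m_1\|_2^2}: 0 for a perfect
#' match, 1 when the registration did nothing. A zero denominator (identical
#' inputs) is reported as r = 0 with a \code{degenerate} attribute.
#'
#' @param m0,m1 template and reference images.
#' @param m_final deformed template.
#' @return scalar; attribute \code{degenerate} is TRUE for identical inputs.
#' @export
relative_residual <- function(m0, m1, m_final) {
  den <- sum((m0 - m1)^2)
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(sum((m_final - m1)^2) / den, degenerate = FALSE)
}

#' Transport a label map along a velocity field
#'
#' Advects each label's indicator function with the semi-Lagrangian solver
#' (linear interpolation, so transported indicators stay in [0, 1]) and
#' rebuilds an integer map: a voxel gets the label whose transported indicator
#' is largest, provided it reaches the 0.5 threshold; ties go to the smaller
#' label id.
#'
#' @param l integer label map.
#' @param v velocity field.
#' @param grid the grid.
#' @param tg a \code{\link{time_grid}}.
#' @return integer label map of the same shape.
#' @export
deform_labels <- function(l, v, grid, tg) {
  labs <- sort(setdiff(unique(as.integer(l)), 0L))
  out <- array(0L, dim = grid$dims)
  best <- array(0, dim = grid$dims)
  for (val in labs) {
    ind <- array(as.numeric(l == val), dim = grid$dims)
    tr <- solve_state(ind, v, grid, tg, scheme = "linear", keep_all = FALSE)
    take <- (tr >= 0.5) & (out == 0L | tr > best)
    out[take] <- val
    best[take] <- tr[take]
  }
  out
}

#' Jacobian-determinant statistics of a velocity field
#'
#' @inheritParams deform_labels
#' @param scheme interpolation scheme for the characteristic tracing.
#' @return numeric vector \code{c(jac_min, jac_max)}.
#' @export
jacobian_stats <- function(v, grid, tg, scheme = "cubic") {
  deformation_map(v, grid, tg, scheme)$jac_range
}
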
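# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shared plane geometry. All image-space computations use pixel coordinates
# with x to the right and y downward (matrix column = x, matrix row = y,
# 1-based). In this frame a positive angular step rotates the heading toward
# the fish's right, so reported angles are right-positive throughout:
# positive delta-theta = rightward turn, positive phi = prey on the right.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotate 2-column coordinates by an angle
#'
#' Algebraic counter-clockwise rotation in (x, y); with y pointing down this
#' is a rightward (clockwise on screen) rotation for positive angles.
#'
#' @param xy numeric vector c(x, y) or 2-column matrix.
#' @param deg rotation angle in degrees.
#' @return rotated coordinates, same shape as `xy`.
#' @keywords internal
rotate_xy <- function(xy, deg) {
  a <- deg2rad(deg)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  if (is.matrix(xy)) xy %*% t(R) else drop(R %*% xy)
}

#' Signed angle from vector a to vector b, degrees in (-180, 180]
#' @keywords internal
signed_angle <- function(a, b) {
  ang <- rad2deg(atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]))
  if (ang <= -180) ang + 360 else ang
}

#' Wrap an angle into (-180, 180]
#' @keywords internal
wrap180 <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Midline vertices for a given pose
#'
#' Builds the 7 vertices of the six-segment midline model: one head segment
#' from snout to neck along the body axis, then five tail segments whose
#' angles `gamma` are measured against the body axis (right-positive).
#'
#' @param snout c(x, y) snout position (pixels).
#' @param theta heading in degrees (direction the snout points).
#' @param gamma numeric length-5, tail segment angles in degrees.
#' @param head_len head-segment length (pixels).
#' @param tail_seg_len single tail-segment length (pixels).
#' @return 7 x 2 matrix of vertices, snout first.
#' @export
midline_vertices <- function(snout, theta, gamma, head_len, tail_seg_len) {
  stopifnot(length(gamma) == 5)
  u <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
  v <- matrix(NA_real_, 7, 2)
  v[1, ] <- snout
  v[2, ] <- snout - head_len * u
  for (i in 1:5) {
    # positive gamma displaces the tail tip toward the fish's right (+y side
    # for a fish heading +x), i.e. the backward direction rotated by -gamma
    d <- rotate_xy(-u, -gamma[i])
    v[i + 2, ] <- v[i + 1, ] + tail_seg_len * d
  }
  v
}

#' Count sign changes of a trace, ignoring near-zero samples
#'
#' @param x numeric trace.
#' @param eps_frac samples with |x| below this fraction of max |x| are
#'   dropped before counting transitions.
#' @keywords internal
count_zero_crossings <- function(x, eps_frac = 1e-6) {
  m <- max(abs(x))
  if (m == 0) return(0L)
  s <- sign(x[abs(x) > eps_frac * m])
  sum(diff(s) != 0)
}
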
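# Quaternion helpers (scalar-first convention, w x y z).
# Quaternions here map head-frame vectors into the Earth frame; rotating an
# Earth-frame vector back into the head frame uses the conjugate.

#' Quaternion product
#'
#' Hamilton product of quaternions in scalar-first (w, x, y, z) convention.
#' Both arguments may be length-4 vectors or n x 4 matrices (recycled
#' row-wise).
#'
#' @param a,b quaternions (length-4 vectors or n x 4 matrices).
#' @return an n x 4 matrix (or length-4 vector if both inputs were vectors).
#' @export
quat_multiply <- function(a, b) {
  va <- is.null(dim(a)); vb <- is.null(dim(b))
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  out <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  if (va && vb) drop(out) else out
}

#' Quaternion conjugate
#' @param q length-4 vector or n x 4 matrix.
#' @return same shape as `q`.
#' @export
quat_conjugate <- function(q) {
  if (is.null(dim(q))) c(q[1], -q[2], -q[3], -q[4])
  else cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Rotate vectors by quaternions
#'
#' Applies the rotation represented by `q` to the 3-vectors `v` (row-wise).
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions.
#' @param v length-3 vector or n x 3 matrix.
#' @return rotated vectors, n x 3 matrix (or length-3 vector).
#' @export
quat_rotate <- function(q, v) {
  vq <- is.null(dim(q)); vv <- is.null(dim(v))
  q <- rbind(q); v <- rbind(v)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  tx <- 2 * (y * v[, 3] - z * v[, 2])
  ty <- 2 * (z * v[, 1] - x * v[, 3])
  tz <- 2 * (x * v[, 2] - y * v[, 1])
  out <- cbind(
    v[, 1] + w * tx + (y * tz - z * ty),
    v[, 2] + w * ty + (z * tx - x * tz),
    v[, 3] + w * tz + (x * ty - y * tx)
  )
  if (vq && vv) drop(out) else out
}

#' Quaternion from a rotation vector
#'
#' `rv` is axis * angle in radians; returns the unit quaternion of that
#' rotation.
#'
#' @param rv length-3 rotation vector (radians).
#' @return length-4 unit quaternion.
#' @export
quat_from_rotvec <- function(rv) {
  a <- sqrt(sum(rv^2))
  if (a < 1e-12) {
    q <- c(1, rv / 2)
  } else {
    q <- c(cos(a / 2), rv / a * sin(a / 2))
  }
  q / sqrt(sum(q^2))
}

#' Geodesic angle of the relative rotation between two quaternions
#'
#' The smallest rotation angle (degrees) taking attitude `q1` to `q2`.
#'
#' @param q1,q2 length-4 unit quaternions.
#' @return angle in degrees, in \[0, 180\].
#' @export
quat_angle <- function(q1, q2) {
  d <- quat_multiply(quat_conjugate(q1), q2)
  w <- min(1, abs(d[1]))
  2 * acos(w) * 180 / pi
}

# angle in degrees between two 3-vectors
vector_angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop_value("cannot measure the angle of a zero vector")
  d <- sum(u * v) / (cu * cv)
  acos(max(-1, min(1, d))) * 180 / pi
}
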
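# Unit-quaternion helpers for rigid-body orientation. Convention:
# q = (w, x, y, z), body-to-lab rotation v_lab = q v q*.

#' Rotate a vector by a unit quaternion
#' @param q quaternion (w, x, y, z).
#' @param v 3-vector or n x 3 matrix of body-frame vectors.
#' @return rotated vector(s) in the lab frame.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else drop(R %*% v)
}

#' Rotation matrix of a unit quaternion
#' @param q quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quaternion product (composition of rotations)
#' @param a,b quaternions (w, x, y, z); `a %*% b` applies `b` first.
#' @return quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion from an axis-angle rotation vector
#' @param w rotation vector (axis * angle, rad).
#' @return unit quaternion.
#' @export
quat_from_rotvec <- function(w) {
  ang <- sqrt(sum(w^2))
  if (ang < 1e-300) return(c(1, 0, 0, 0))
  c(cos(ang / 2), sin(ang / 2) * w / ang)
}

#' Uniform random unit quaternion
#'
#' Normalised 4-variate standard normal, uniform on the rotation group.
#' Uses the current R RNG stream.
#' @return unit quaternion.
#' @export
quat_random <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}
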
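#' Rotation helpers (unit quaternions, scalar-first)
#'
#' Quaternions are stored scalar-first, `c(qw, qx, qy, qz)`, and represent the
#' rotation taking camera-frame (or sensor-frame) vectors into the tracker
#' (world) frame. All rotation matrices are 3x3 orthonormal with determinant +1.
#'
#' @param q numeric length-4 quaternion, scalar first.
#' @return `quat_to_rotmat()` returns a 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- normalize_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_rotmat
#' @param R 3x3 rotation matrix.
#' @return `rotmat_to_quat()` returns a unit quaternion with non-negative
#'   scalar part.
#' @export
rotmat_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  normalize_quat(q)
}

#' @rdname quat_to_rotmat
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return `quat_from_axis_angle()` returns the corresponding unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis has zero length")
  a <- angle_deg * pi / 180
  c(cos(a / 2), sin(a / 2) * axis / n)
}

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

normalize_quat <- function(q, tol = 1e-6) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > tol)
    stop(sprintf("quaternion norm %.8f departs from 1 by more than %g", n, tol))
  q / n
}

rotation_angle_deg <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ca))) * 180 / pi
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
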
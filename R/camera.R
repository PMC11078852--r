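#' Camera intrinsics
#'
#' Pinhole intrinsics with optional Brown-Conrady distortion. The camera frame
#' is right-handed with the optical axis along +z, image x to the right and
#' image y down; pixel coordinates are 0-based with (0, 0) at the centre of the
#' top-left pixel.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels, inside the image.
#' @param image_width,image_height image size in pixels.
#' @param distortion numeric vector `c(k1, k2, k3, p1, p2)` of radial (k) and
#'   tangential (p) coefficients, or an empty vector for an ideal pinhole.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, image_width, image_height,
                              distortion = numeric(0)) {
  stopifnot(fx > 0, fy > 0,
            cx >= 0, cx < image_width,
            cy >= 0, cy < image_height,
            length(distortion) %in% c(0L, 5L))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 distortion = as.numeric(distortion)),
            class = "camera_intrinsics")
}

#' Camera/sensor pose in tracker coordinates
#'
#' A rigid transform placing the tracked sensor (and, through the rig's
#' hand-eye transform, the camera) in the electromagnetic tracker frame.
#'
#' @param position length-3 numeric, mm, tracker frame.
#' @param quaternion unit quaternion `c(qw, qx, qy, qz)` rotating sensor-frame
#'   vectors into the tracker frame.
#' @param frame_id identifier of the video frame this pose belongs to.
#' @param timestamp optional acquisition time in seconds.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(position, quaternion, frame_id = NA_character_,
                        timestamp = NA_real_) {
  stopifnot(length(position) == 3, all(is.finite(position)))
  q <- normalize_quat(quaternion)
  structure(list(position = as.numeric(position), quaternion = q,
                 frame_id = as.character(frame_id),
                 timestamp = as.numeric(timestamp)),
            class = "camera_pose")
}

#' Rig configuration: intrinsics plus hand-eye transform
#'
#' The hand-eye transform is the fixed rigid transform from the tracked sensor
#' frame to the camera optical frame: `x_cam = R %*% x_sensor + t`.
#'
#' @param intrinsics a [camera_intrinsics()] object.
#' @param hand_eye_rotation 3x3 rotation matrix (sensor to camera), identity by
#'   default.
#' @param hand_eye_translation length-3 translation in mm, zero by default.
#' @return An object of class `rig_config`.
#' @export
rig_config <- function(intrinsics,
                       hand_eye_rotation = diag(3),
                       hand_eye_translation = c(0, 0, 0)) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            is.matrix(hand_eye_rotation), all(dim(hand_eye_rotation) == c(3, 3)),
            length(hand_eye_translation) == 3)
  R <- hand_eye_rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("hand_eye rotation must be orthonormal with determinant +1")
  structure(list(intrinsics = intrinsics,
                 hand_eye_rotation = R,
                 hand_eye_translation = as.numeric(hand_eye_translation)),
            class = "rig_config")
}

# Camera extrinsics in world coordinates after composing pose with hand-eye:
# returns list(R = world-from-camera rotation, C = camera centre in mm).
camera_extrinsics <- function(pose, rig) {
  R_ws <- quat_to_rotmat(pose$quaternion)
  R_cs <- rig$hand_eye_rotation
  t_cs <- rig$hand_eye_translation
  R_wc <- R_ws %*% t(R_cs)
  C <- pose$position - as.numeric(R_wc %*% t_cs)
  list(R = R_wc, C = C)
}

apply_distortion <- function(xn, yn, d) {
  if (length(d) == 0) return(cbind(xn, yn))
  k1 <- d[1]; k2 <- d[2]; k3 <- d[3]; p1 <- d[4]; p2 <- d[5]
  r2 <- xn^2 + yn^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  cbind(xd, yd)
}

# Iterative inversion of apply_distortion (fixed point), per point.
remove_distortion <- function(xd, yd, d, max_iter = 50, tol = 1e-12) {
  if (length(d) == 0) return(cbind(xd, yd))
  xn <- xd; yn <- yd
  for (i in seq_len(max_iter)) {
    dist <- apply_distortion(xn, yn, d)
    ex <- dist[, 1] - xd
    ey <- dist[, 2] - yd
    xn <- xn - ex
    yn <- yn - ey
    if (max(abs(ex), abs(ey)) < tol) return(cbind(xn, yn))
  }
  stop(sprintf("undistortion did not converge after %d iterations", max_iter))
}

#' Project 3D points into an image
#'
#' Forward pinhole projection of tracker-frame points through a posed camera.
#'
#' @param points3d length-3 numeric or nx3 matrix of points, mm, tracker frame.
#' @param pose a [camera_pose()].
#' @param rig a [rig_config()].
#' @return nx2 matrix of pixel coordinates (columns u, v).
#' @details Points at or behind the camera plane (non-positive depth along the
#'   optical axis) are rejected with an error.
#' @export
project_points <- function(points3d, pose, rig) {
  X <- if (is.matrix(points3d)) points3d else matrix(points3d, ncol = 3)
  ext <- camera_extrinsics(pose, rig)
  Xc <- sweep(X, 2, ext$C) %*% ext$R # (X - C) %*% R_wc == t(R_cw %*% t(X-C))
  z <- Xc[, 3]
  if (any(z <= 1e-9))
    stop("behind camera: point(s) with non-positive depth cannot be projected")
  xy <- apply_distortion(Xc[, 1] / z, Xc[, 2] / z, rig$intrinsics$distortion)
  K <- rig$intrinsics
  cbind(u = K$fx * xy[, 1] + K$cx, v = K$fy * xy[, 2] + K$cy)
}

#' Back-project a pixel to a viewing ray
#'
#' @param pixel length-2 numeric (u, v) in pixels.
#' @param pose a [camera_pose()].
#' @param rig a [rig_config()].
#' @return A `ray` object: list with `origin` (camera centre, mm, tracker
#'   frame) and unit `direction` pointing into the scene.
#' @export
backproject_ray <- function(pixel, pose, rig) {
  stopifnot(length(pixel) == 2, all(is.finite(pixel)))
  K <- rig$intrinsics
  xd <- (pixel[1] - K$cx) / K$fx
  yd <- (pixel[2] - K$cy) / K$fy
  und <- remove_distortion(xd, yd, K$distortion)
  ext <- camera_extrinsics(pose, rig)
  d <- unit3(as.numeric(ext$R %*% c(und[1, 1], und[1, 2], 1)))
  structure(list(origin = ext$C, direction = d), class = "ray")
}

#' Relative motion between two posed cameras
#'
#' Scalar motion descriptors of an image pair: inter-centre translation,
#' relative rotation angle, and the angle between the translation vector and
#' the mean optical axis (small values indicate near pure forward-backward
#' motion, the degenerate geometry for two-view triangulation).
#'
#' @param pose_a,pose_b [camera_pose()] objects.
#' @param rig a [rig_config()]; identity hand-eye by default.
#' @return list with `translation_mm`, `rotation_deg` (in \[0, 180\]) and
#'   `translation_axis_angle_deg` (in \[0, 90\]; 0 by convention for identical
#'   centres).
#' @export
relative_motion <- function(pose_a, pose_b, rig = NULL) {
  if (is.null(rig))
    rig <- rig_config(camera_intrinsics(1, 1, 0, 0, 2, 2))
  ea <- camera_extrinsics(pose_a, rig)
  eb <- camera_extrinsics(pose_b, rig)
  t_vec <- eb$C - ea$C
  translation <- sqrt(sum(t_vec^2))
  rotation <- rotation_angle_deg(t(ea$R) %*% eb$R)
  if (translation < 1e-12) {
    axis_angle <- 0
  } else {
    z_mean <- ea$R[, 3] + eb$R[, 3]
    nz <- sqrt(sum(z_mean^2))
    if (nz < 1e-12) z_mean <- ea$R[, 3] else z_mean <- z_mean / nz
    ca <- abs(sum(t_vec / translation * z_mean)) # |cos|: folds into [0, 90]
    axis_angle <- rad2deg(acos(max(-1, min(1, ca))))
  }
  list(translation_mm = translation,
       rotation_deg = rotation,
       translation_axis_angle_deg = axis_angle)
}

#' Triangulate a point from two viewing rays
#'
#' Midpoint of the common perpendicular segment between two rays; the segment
#' length is reported as the triangulation residual (0 mm for rays that
#' intersect exactly).
#'
#' @param ray_a,ray_b `ray` objects from [backproject_ray()].
#' @param min_sin lower bound on the sine of the angle between ray directions;
#'   below it the geometry is declared degenerate.
#' @return list with `point3d` (mm) and `residual_mm`.
#' @export
triangulate_pair <- function(ray_a, ray_b, min_sin = 1e-6) {
  d1 <- ray_a$direction; d2 <- ray_b$direction
  s <- sqrt(sum(cross3(d1, d2)^2))
  if (s < min_sin)
    stop(sprintf(
      "degenerate geometry: rays are near-parallel (angle %.3g deg)",
      rad2deg(asin(max(-1, min(1, s))))))
  w0 <- ray_a$origin - ray_b$origin
  b <- sum(d1 * d2)
  d <- sum(d1 * w0)
  e <- sum(d2 * w0)
  denom <- 1 - b^2
  t1 <- (b * e - d) / denom
  t2 <- (e - b * d) / denom
  p1 <- ray_a$origin + t1 * d1
  p2 <- ray_b$origin + t2 * d2
  list(point3d = (p1 + p2) / 2, residual_mm = sqrt(sum((p1 - p2)^2)))
}
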
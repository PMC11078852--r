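#' Default synthetic endoscope rig
#'
#' Wide field-of-view endoscope-like intrinsics: 640x640 pixels, fx = fy = 330
#' (about 88 degrees horizontal FOV), principal point at the image centre,
#' zero distortion, identity hand-eye transform. All values configurable
#' through [camera_intrinsics()] / [rig_config()].
#'
#' @return A [rig_config()].
#' @export
default_rig <- function() {
  rig_config(camera_intrinsics(fx = 330, fy = 330, cx = 319.5, cy = 319.5,
                               image_width = 640, image_height = 640))
}

#' Generate a synthetic polyp border curve
#'
#' A planar ellipse of known axes, optionally perturbed out-of-plane by a
#' smooth periodic displacement (a stand-in for asymmetric, non-rigid polyp
#' borders). The stored ground truth is the generating major axis.
#'
#' @param major_mm,minor_mm full axis lengths in mm (`major >= minor > 0`);
#'   the default generator range for the cohort simulations is 5-20 mm.
#' @param centre polyp centre in tracker coordinates (mm).
#' @param normal plane normal (unit vector after normalization).
#' @param theta_deg in-plane rotation of the major axis.
#' @param waviness_mm amplitude of the out-of-plane periodic perturbation.
#' @param n_points number of border samples.
#' @param seed RNG seed for the perturbation phase/frequency.
#' @return An object of class `synthetic_polyp` with `border3d` (nx3 mm),
#'   `true_major_axis_mm`, `true_minor_axis_mm`, `centre`, `normal`,
#'   `perturbation_amp_mm`.
#' @export
make_polyp <- function(major_mm, minor_mm, centre = c(0, 0, 0),
                       normal = c(0, 0, 1), theta_deg = 0,
                       waviness_mm = 0, n_points = 200, seed = NULL) {
  if (!(major_mm >= minor_mm && minor_mm > 0))
    stop("invalid axes: need major_mm >= minor_mm > 0")
  stopifnot(n_points >= 6)
  nrm <- unit3(normal)
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit3(cross3(ref, nrm))
  e2 <- cross3(nrm, e1)
  th <- deg2rad(theta_deg)
  u1 <- cos(th) * e1 + sin(th) * e2
  u2 <- -sin(th) * e1 + cos(th) * e2
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  a <- major_mm / 2; b <- minor_mm / 2
  w <- rep(0, n_points)
  if (waviness_mm > 0) {
    par <- with_seed(seed, list(m = sample(2:5, 1), phase = stats::runif(1, 0, 2 * pi)))
    w <- waviness_mm * sin(par$m * t + par$phase)
  }
  pts <- t(vapply(seq_along(t), function(i)
    centre + a * cos(t[i]) * u1 + b * sin(t[i]) * u2 + w[i] * nrm,
    numeric(3)))
  structure(list(border3d = pts,
                 true_major_axis_mm = major_mm,
                 true_minor_axis_mm = minor_mm,
                 centre = as.numeric(centre), normal = nrm,
                 perturbation_amp_mm = waviness_mm),
            class = "synthetic_polyp")
}

# Look-at camera pose: optical axis (+z) toward `target`, roll about the axis.
look_at_pose <- function(position, target, roll_deg = 0, frame_id = NA) {
  z <- unit3(target - position)
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- unit3(cross3(ref, z))
  y <- cross3(z, x)
  R <- cbind(x, y, z)
  if (roll_deg != 0)
    R <- R %*% quat_to_rotmat(quat_from_axis_angle(c(0, 0, 1), roll_deg))
  camera_pose(position, rotmat_to_quat(R), frame_id = frame_id)
}

#' Generate an endoscope-like set of viewing poses
#'
#' Cameras look at the polyp centre from distances near the working distance,
#' with lateral offsets arranged so that every pair of views has an
#' inter-centre translation within `baseline_mm`, relative rotation below 30
#' degrees, and a translation direction well away from the optical axis (no
#' pure forward-backward pairs). Generation is deterministic under `seed` and
#' retried until the constraints hold.
#'
#' @param polyp a [make_polyp()] object.
#' @param n_views number of views (>= 2).
#' @param working_distance_mm camera-to-polyp distance (default 60 mm).
#' @param baseline_mm length-2 range for pairwise translations (mm).
#' @param seed RNG seed.
#' @param max_tries retry budget for constraint satisfaction.
#' @return list of [camera_pose()] objects (sensor poses under an identity
#'   hand-eye transform).
#' @export
make_pose_set <- function(polyp, n_views = 5, working_distance_mm = 60,
                          baseline_mm = c(5, 25), seed = NULL,
                          max_tries = 200) {
  stopifnot(n_views >= 2, length(baseline_mm) == 2,
            baseline_mm[1] < baseline_mm[2], working_distance_mm > 0)
  ctr <- polyp$centre
  view_dir <- -polyp$normal # look at the polyp from its face side
  ref <- if (abs(view_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unit3(cross3(ref, view_dir))
  b2 <- cross3(view_dir, b1)
  rho <- (baseline_mm[1] + baseline_mm[2]) / 4
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ang <- 2 * pi * (seq_len(n_views) - 1) / n_views +
        stats::rnorm(n_views, 0, pi / (6 * n_views))
      axial <- stats::runif(n_views, -1, 1) * min(2, baseline_mm[2] / 8)
      roll <- stats::runif(n_views, -5, 5)
      centres <- lapply(seq_len(n_views), function(i)
        ctr - (working_distance_mm + axial[i]) * view_dir +
          rho * cos(ang[i]) * b1 + rho * sin(ang[i]) * b2)
      poses <- lapply(seq_len(n_views), function(i)
        look_at_pose(centres[[i]], ctr, roll_deg = roll[i],
                     frame_id = sprintf("f%02d", i)))
      # pairwise constraints: translation inside the baseline range, rotation
      # below 30 degrees, translation direction away from the optical axis
      # (the minimal-movement rule is governed by the baseline range itself)
      ok <- TRUE
      for (i in seq_len(n_views - 1)) for (j in (i + 1):n_views) {
        m <- relative_motion(poses[[i]], poses[[j]])
        if (m$translation_mm < baseline_mm[1] ||
            m$translation_mm > baseline_mm[2] ||
            m$rotation_deg >= 30 ||
            m$translation_axis_angle_deg < 15) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(poses)
    }
    stop(sprintf(
      "pose generation failed: constraints unsatisfied after %d tries (baseline %g-%g mm, %d views)",
      max_tries, baseline_mm[1], baseline_mm[2], n_views))
  })
}

#' Assemble a synthetic scene
#'
#' @param polyp a [make_polyp()] object.
#' @param poses list of [camera_pose()] (e.g. from [make_pose_set()]).
#' @param rig a [rig_config()]; [default_rig()] by default.
#' @param landmark length-3 landmark position (mm).
#' @param pose_pos_sigma_mm,pose_rot_sigma_deg,pixel_sigma_px noise standard
#'   deviations applied by [render_views()]: Gaussian position and rotation
#'   noise on the reported poses, Gaussian pixel noise on the contours.
#' @param seed RNG seed driving all scene randomness.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(polyp, poses, rig = default_rig(),
                            landmark = c(0, 0, 200),
                            pose_pos_sigma_mm = 0.3,
                            pose_rot_sigma_deg = 0.3,
                            pixel_sigma_px = 0.5,
                            seed = 1L) {
  stopifnot(inherits(polyp, "synthetic_polyp"), length(poses) >= 2,
            length(landmark) == 3)
  structure(list(polyp = polyp, poses = poses, rig = rig,
                 landmark = as.numeric(landmark),
                 noise = list(pose_pos_sigma_mm = pose_pos_sigma_mm,
                              pose_rot_sigma_deg = pose_rot_sigma_deg,
                              pixel_sigma_px = pixel_sigma_px),
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Even-odd scanline rasterization of a closed polygon into a binary mask.
rasterize_polygon <- function(pts, width, height) {
  px <- matrix(0L, nrow = height, ncol = width)
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (row in seq_len(height)) {
    yc <- row - 1
    crossing <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
    if (!any(crossing)) next
    xs <- x[crossing] + (yc - y[crossing]) *
      (x2[crossing] - x[crossing]) / (y2[crossing] - y[crossing])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (hi >= lo)
        px[row, max(1, lo + 1):min(width, hi + 1)] <- 1L
    }
  }
  px
}

#' Render a synthetic scene into masks, contours and noisy poses
#'
#' The polyp border is projected through each (true) pose; the mask is the
#' filled projected polygon, the contour the exact projected points plus
#' Gaussian pixel noise, and the reported poses carry Gaussian position and
#' rotation noise, emulating an electromagnetic tracker. All randomness
#' derives from the scene seed.
#'
#' @param scene a [synthetic_scene()].
#' @return list with `masks` (list of [segmentation_mask()]), `contours`
#'   (list of [border_contour()]; one point per border sample, index-aligned
#'   across views), `noisy_poses`, `true_poses`, `rig`, `landmark`, `truth`
#'   (true size, centre, landmark distance).
#' @export
render_views <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  K <- scene$rig$intrinsics
  n <- length(scene$poses)
  with_seed(scene$seed, {
    masks <- vector("list", n)
    contours <- vector("list", n)
    noisy <- vector("list", n)
    for (i in seq_len(n)) {
      pose <- scene$poses[[i]]
      uv <- project_points(scene$polyp$border3d, pose, scene$rig)
      if (any(uv[, 1] < 0) || any(uv[, 1] > K$image_width - 1) ||
          any(uv[, 2] < 0) || any(uv[, 2] > K$image_height - 1))
        stop(sprintf("polyp out of frame in view %s", pose$frame_id))
      masks[[i]] <- segmentation_mask(
        rasterize_polygon(uv, K$image_width, K$image_height),
        frame_id = pose$frame_id)
      uv_noisy <- uv
      if (scene$noise$pixel_sigma_px > 0)
        uv_noisy <- uv + matrix(stats::rnorm(length(uv), 0,
                                             scene$noise$pixel_sigma_px),
                                ncol = 2)
      contours[[i]] <- border_contour(uv_noisy, closed = TRUE,
                                      frame_id = pose$frame_id)
      pos <- pose$position
      q <- pose$quaternion
      if (scene$noise$pose_pos_sigma_mm > 0)
        pos <- pos + stats::rnorm(3, 0, scene$noise$pose_pos_sigma_mm)
      if (scene$noise$pose_rot_sigma_deg > 0) {
        axis <- unit3(stats::rnorm(3))
        ang <- stats::rnorm(1, 0, scene$noise$pose_rot_sigma_deg)
        q <- quat_mul(quat_from_axis_angle(axis, ang), q)
      }
      noisy[[i]] <- camera_pose(pos, q, frame_id = pose$frame_id,
                                timestamp = pose$timestamp)
    }
    list(masks = masks, contours = contours, noisy_poses = noisy,
         true_poses = scene$poses, rig = scene$rig,
         landmark = scene$landmark,
         truth = list(size_mm = scene$polyp$true_major_axis_mm,
                      centre = scene$polyp$centre,
                      location_mm = sqrt(sum((scene$polyp$centre -
                                                scene$landmark)^2))))
  })
}

#' Simulate a cohort of polyps and measure each end-to-end
#'
#' The repository's stand-in for an ex vivo validation session: for each
#' polyp, a border curve with major axis uniform in `major_range_mm` (and
#' aspect ratio minor/major uniform in `aspect_range`) is generated at a
#' random position and orientation, viewed from `n_views` endoscope-like
#' poses at the working distance, rendered with the configured tracker and
#' pixel noise, and measured with the full pipeline. The landmark is placed
#' at a random direction `landmark_range_mm` away from the polyp centre.
#'
#' @param n_polyps cohort size.
#' @param base_seed integer seed; polyp i uses seeds derived from
#'   `base_seed * 1000 + i`.
#' @param major_range_mm,aspect_range generator ranges for the border axes.
#' @param n_views views per polyp.
#' @param working_distance_mm camera distance.
#' @param baseline_mm pairwise translation range for the pose set.
#' @param landmark_range_mm range of true landmark distances.
#' @param pose_pos_sigma_mm,pose_rot_sigma_deg,pixel_sigma_px noise levels.
#' @param waviness_mm out-of-plane border perturbation amplitude.
#' @param correspondence `"shape_context"` (full pipeline) or `"exact"`.
#' @param ... further arguments passed to [measure_polyp()].
#' @return data.frame with one row per polyp: true and estimated size and
#'   landmark distance, their errors, and the number of pairs used.
#' @export
simulate_cohort <- function(n_polyps = 30, base_seed = 1,
                            major_range_mm = c(5, 20),
                            aspect_range = c(0.5, 0.95),
                            n_views = 5,
                            working_distance_mm = 60,
                            baseline_mm = c(5, 25),
                            landmark_range_mm = c(150, 250),
                            pose_pos_sigma_mm = 0.3,
                            pose_rot_sigma_deg = 0.3,
                            pixel_sigma_px = 0.5,
                            waviness_mm = 0,
                            correspondence = "shape_context", ...) {
  stopifnot(n_polyps >= 1, base_seed < 2^31 / 1000 - 1)
  rows <- vector("list", n_polyps)
  for (i in seq_len(n_polyps)) {
    s <- base_seed * 1000 + i
    par <- with_seed(s, list(
      major = stats::runif(1, major_range_mm[1], major_range_mm[2]),
      aspect = stats::runif(1, aspect_range[1], aspect_range[2]),
      normal = c(stats::rnorm(2, 0, 0.2), 1),
      theta = stats::runif(1, 0, 180),
      centre = stats::rnorm(3, 0, 30),
      lm_dir = unit3(stats::rnorm(3)),
      lm_dist = stats::runif(1, landmark_range_mm[1], landmark_range_mm[2])))
    polyp <- make_polyp(par$major, par$major * par$aspect,
                        centre = par$centre, normal = par$normal,
                        theta_deg = par$theta, waviness_mm = waviness_mm,
                        seed = s)
    poses <- make_pose_set(polyp, n_views = n_views,
                           working_distance_mm = working_distance_mm,
                           baseline_mm = baseline_mm, seed = s + 1)
    landmark <- par$centre + par$lm_dist * par$lm_dir
    scene <- synthetic_scene(polyp, poses, landmark = landmark,
                             pose_pos_sigma_mm = pose_pos_sigma_mm,
                             pose_rot_sigma_deg = pose_rot_sigma_deg,
                             pixel_sigma_px = pixel_sigma_px, seed = s + 2)
    r <- render_views(scene)
    frames <- Map(function(ct, p) list(contour = ct, pose = p),
                  r$contours, r$noisy_poses)
    m <- measure_polyp(frames, r$rig, r$landmark,
                       correspondence = correspondence, ...)
    rows[[i]] <- data.frame(
      polyp = i,
      true_size_mm = r$truth$size_mm,
      est_size_mm = m$final_size_mm,
      size_error_mm = m$final_size_mm - r$truth$size_mm,
      true_location_mm = r$truth$location_mm,
      est_location_mm = m$final_location_mm,
      location_error_mm = m$final_location_mm - r$truth$location_mm,
      n_pairs_used = m$n_pairs_used)
  }
  do.call(rbind, rows)
}
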
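#' Triangulate matched border points into 3D
#'
#' Each correspondence is back-projected from both views and triangulated by
#' the midpoint of the common perpendicular between the two rays. Points whose
#' triangulation residual exceeds `residual_cap_mm` (mismatched
#' correspondences) are dropped.
#'
#' @param corr a `correspondence_set` from [match_shapes()] or
#'   [exact_correspondences()].
#' @param pose_a,pose_b [camera_pose()] objects for the two frames.
#' @param rig a [rig_config()].
#' @param residual_cap_mm drop points with residual above this (default 2 mm).
#' @param min_epipolar_sin drop correspondences where the sine of the angle
#'   between the second view's contour tangent and the epipolar direction is
#'   below this: near epipolar tangency the match position along the border
#'   is unconstrained and triangulation degenerates along the curve. 0
#'   disables the filter.
#' @param thresholds motion-quality thresholds; the pair must pass
#'   [check_pair()] unless `override_motion_check`.
#' @param override_motion_check skip the motion-quality gate.
#' @return An object of class `border3d`: `points` (nx3 mm, tracker frame),
#'   `residuals_mm`, `source_pair`.
#' @export
reconstruct_border <- function(corr, pose_a, pose_b, rig,
                               residual_cap_mm = 2,
                               min_epipolar_sin = 0,
                               thresholds = motion_thresholds(),
                               override_motion_check = FALSE) {
  stopifnot(inherits(corr, "correspondence_set"))
  if (!override_motion_check) {
    qrep <- check_pair(pose_a, pose_b, thresholds, rig)
    if (!qrep$passed)
      stop(sprintf("pair (%s, %s) fails motion-quality rules: %s",
                   pose_a$frame_id, pose_b$frame_id,
                   paste(qrep$failed_rules, collapse = ", ")))
  }
  n <- nrow(corr$pairs)
  if (n < 6) stop("reconstruction needs at least 6 correspondences")
  ra <- backproject_rays(corr$points_p[corr$pairs[, 1], , drop = FALSE],
                         pose_a, rig)
  rb <- backproject_rays(corr$points_q[corr$pairs[, 2], , drop = FALSE],
                         pose_b, rig)
  tri <- triangulate_rays(ra, rb)
  res <- tri$residual_mm
  keep <- is.finite(res) & res <= residual_cap_mm
  if (min_epipolar_sin > 0)
    keep <- keep & epipolar_tangent_sin(corr, pose_a, pose_b, rig) >=
      min_epipolar_sin
  if (sum(keep) < 6) {
    h <- stats::quantile(res[is.finite(res)], c(0, 0.25, 0.5, 0.75, 1),
                         na.rm = TRUE)
    stop(sprintf(paste0(
      "reconstruction failed: only %d/%d points kept under the %.3g mm ",
      "residual cap (residual quartiles: %s mm)"),
      sum(keep), n, residual_cap_mm,
      paste(signif(h, 3), collapse = ", ")))
  }
  structure(list(points = tri$points[keep, , drop = FALSE],
                 residuals_mm = res[keep],
                 source_pair = c(pose_a$frame_id, pose_b$frame_id)),
            class = "border3d")
}

# Vectorized ray bundle: origins (camera centre) + unit directions for a
# matrix of pixels. Equals backproject_ray row by row.
backproject_rays <- function(pixels, pose, rig) {
  K <- rig$intrinsics
  xd <- (pixels[, 1] - K$cx) / K$fx
  yd <- (pixels[, 2] - K$cy) / K$fy
  und <- remove_distortion(xd, yd, K$distortion)
  ext <- camera_extrinsics(pose, rig)
  D <- cbind(und[, 1], und[, 2], 1) %*% t(ext$R)
  D <- D / sqrt(rowSums(D^2))
  list(origin = ext$C, directions = D)
}

# Vectorized midpoint triangulation of paired ray bundles; residual is NA
# where rays are near-parallel.
triangulate_rays <- function(ra, rb, min_sin = 1e-6) {
  d1 <- ra$directions; d2 <- rb$directions
  n <- nrow(d1)
  w0 <- matrix(ra$origin - rb$origin, n, 3, byrow = TRUE)
  b <- rowSums(d1 * d2)
  sin2 <- pmax(0, 1 - b^2)
  d <- rowSums(d1 * w0)
  e <- rowSums(d2 * w0)
  t1 <- (b * e - d) / sin2
  t2 <- (e - b * d) / sin2
  P1 <- matrix(ra$origin, n, 3, byrow = TRUE) + t1 * d1
  P2 <- matrix(rb$origin, n, 3, byrow = TRUE) + t2 * d2
  res <- sqrt(rowSums((P1 - P2)^2))
  bad <- sqrt(sin2) < min_sin
  res[bad] <- NA_real_
  list(points = (P1 + P2) / 2, residual_mm = res)
}

# Per-correspondence |sin| of the angle between the epipolar direction in
# view B and the contour tangent of Q at the matched point. Small values mean
# the epipolar line runs along the border: the correspondence is
# ill-conditioned tangentially.
epipolar_tangent_sin <- function(corr, pose_a, pose_b, rig) {
  n <- nrow(corr$pairs)
  ra <- backproject_rays(corr$points_p[corr$pairs[, 1], , drop = FALSE],
                         pose_a, rig)
  eb <- camera_extrinsics(pose_b, rig)
  K <- rig$intrinsics
  proj_b <- function(X) { # project without behind-camera errors (NA instead)
    Xc <- sweep(X, 2, eb$C) %*% eb$R
    z <- Xc[, 3]
    z[z <= 1e-9] <- NA
    xy <- apply_distortion(Xc[, 1] / z, Xc[, 2] / z, K$distortion)
    cbind(K$fx * xy[, 1] + K$cx, K$fy * xy[, 2] + K$cy)
  }
  u1 <- proj_b(matrix(ra$origin, n, 3, byrow = TRUE) + 40 * ra$directions)
  u2 <- proj_b(matrix(ra$origin, n, 3, byrow = TRUE) + 80 * ra$directions)
  epi <- u2 - u1
  epi_n <- sqrt(rowSums(epi^2))
  nq <- nrow(corr$points_q)
  jdx <- corr$pairs[, 2]
  tng <- corr$points_q[(jdx %% nq) + 1, , drop = FALSE] -
    corr$points_q[((jdx - 2) %% nq) + 1, , drop = FALSE]
  tng_n <- sqrt(rowSums(tng^2))
  s <- abs(epi[, 1] * tng[, 2] - epi[, 2] * tng[, 1]) / (epi_n * tng_n)
  s[!is.finite(s)] <- 1 # keep points we cannot assess
  s
}

#' Fit a planar ellipse to reconstructed 3D border points
#'
#' The best-fit plane is taken through the centroid, normal to the smallest
#' principal direction; points are orthogonally projected into the plane and a
#' 2D ellipse is fitted by the direct least-squares conic method constrained
#' to ellipses (Fitzgibbon, in the numerically stable Halir-Flusser form).
#' The full major-axis length is the clinically reported longest length.
#'
#' @param border a `border3d` object or an nx3 matrix of points (mm).
#' @return An object of class `ellipse_fit3d`: `centre` (mm), unit `normal`,
#'   `major_axis_mm` and `minor_axis_mm` (full lengths), unit
#'   `major_direction` in the fit plane, and `rms_fit_error_mm` (RMS radial
#'   distance of the points from the fitted ellipse, in-plane).
#' @export
fit_ellipse_3d <- function(border) {
  X <- if (inherits(border, "border3d")) border$points else as.matrix(border)
  stopifnot(ncol(X) == 3)
  n <- nrow(X)
  if (n < 6) stop("ellipse fitting needs at least 6 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are collinear: no plane can be fitted")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  uv <- Xc %*% cbind(e1, e2)
  fit <- fit_ellipse_2d(uv[, 1], uv[, 2])
  centre3 <- ctr + fit$centre[1] * e1 + fit$centre[2] * e2
  major_dir3 <- unit3(fit$major_dir[1] * e1 + fit$major_dir[2] * e2)
  structure(list(centre = as.numeric(centre3),
                 normal = as.numeric(nrm),
                 major_axis_mm = 2 * fit$a,
                 minor_axis_mm = 2 * fit$b,
                 major_direction = major_dir3,
                 rms_fit_error_mm = fit$rms_error),
            class = "ellipse_fit3d")
}

# Direct least-squares ellipse fit (Halir & Flusser formulation of the
# Fitzgibbon method): conic a x^2 + b xy + c y^2 + d x + e y + f = 0 with the
# ellipse constraint 4ac - b^2 = 1 enforced through a generalized eigenproblem.
fit_ellipse_2d <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-14) stop("degenerate conic fit: rank-deficient design")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  idx <- which(cond > 1e-12)
  if (length(idx) == 0) stop("degenerate conic fit: no ellipse solution")
  a1 <- ev[, idx[1]]
  coef <- c(a1, as.numeric(Tm %*% a1)) # (A, B, C, D, E, F)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("degenerate conic fit: not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / eq$values # squared semi-axes along eigen directions
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop("degenerate conic fit: non-positive axis lengths")
  semi <- sqrt(ax2)
  major_i <- which.max(semi)
  a <- semi[major_i]; b <- semi[-major_i]
  major_dir <- eq$vectors[, major_i]
  # radial residuals: distance between each point and the ellipse along the
  # ray from the centre
  minor_dir <- eq$vectors[, -major_i]
  px <- cbind(x - x0, y - y0) %*% cbind(major_dir, minor_dir)
  phi <- atan2(px[, 2], px[, 1])
  r_pt <- sqrt(rowSums(px^2))
  r_el <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  structure(list(centre = c(x0, y0), a = a, b = b,
                 major_dir = major_dir,
                 rms_error = sqrt(mean((r_pt - r_el)^2)),
                 coef = coef),
            class = "ellipse_fit2d")
}

#' Distance from a fitted polyp centre to an anatomical landmark
#'
#' Straight-line Euclidean distance in tracker coordinates, e.g. from the
#' polyp centre to the oesophago-gastric junction.
#'
#' @param fit an `ellipse_fit3d` object (or a length-3 centre).
#' @param landmark length-3 landmark position, mm, tracker frame.
#' @return scalar distance in mm.
#' @export
landmark_distance <- function(fit, landmark) {
  ctr <- if (inherits(fit, "ellipse_fit3d")) fit$centre else as.numeric(fit)
  stopifnot(length(ctr) == 3, length(landmark) == 3,
            all(is.finite(ctr)), all(is.finite(landmark)))
  sqrt(sum((ctr - landmark)^2))
}

#' Pool per-pair estimates with quartile-based outlier rejection
#'
#' If the polyp is stationary, the reconstructed centre should agree across
#' image pairs; pairs whose centre lies far from the component-wise median
#' centre (beyond the Tukey fence `Q3 + iqr_k * IQR` on centre-to-median
#' distances) are flagged as outliers and excluded. Final size and location
#' are arithmetic means over the remaining pairs.
#'
#' @param estimates data.frame (or list of lists) with columns/fields
#'   `size_mm`, `location_mm` and a `centre` matrix (nx3) or per-element
#'   centre vectors.
#' @param iqr_k Tukey fence multiplier (default 1.5).
#' @return An object of class `polyp_measurement` (without per-pair
#'   diagnostics; [measure_polyp()] attaches those).
#' @export
aggregate_pairs <- function(estimates, iqr_k = 1.5) {
  if (length(estimates) == 0) stop("no estimates to aggregate")
  est <- normalize_estimates(estimates)
  n <- nrow(est$centres)
  med <- apply(est$centres, 2, stats::median)
  d <- sqrt(rowSums(sweep(est$centres, 2, med)^2))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + iqr_k * (q[2] - q[1])
  outlier <- d > fence
  if (all(outlier)) outlier[which.min(d)] <- FALSE
  keep <- !outlier
  structure(list(per_pair = data.frame(size_mm = est$size,
                                       location_mm = est$location),
                 centres = est$centres,
                 outlier_flags = outlier,
                 final_size_mm = mean(est$size[keep]),
                 final_location_mm = mean(est$location[keep]),
                 n_pairs_used = sum(keep)),
            class = "polyp_measurement")
}

normalize_estimates <- function(estimates) {
  if (is.data.frame(estimates)) {
    ctr <- as.matrix(estimates[, c("cx", "cy", "cz")])
    list(size = estimates$size_mm, location = estimates$location_mm,
         centres = ctr)
  } else {
    list(size = vapply(estimates, function(e) e$size_mm, 0),
         location = vapply(estimates, function(e) e$location_mm, 0),
         centres = do.call(rbind, lapply(estimates, function(e)
           as.numeric(e$centre))))
  }
}

#' Measure a polyp from multiple tracked frames
#'
#' End-to-end orchestration: refine masks, extract and resample borders,
#' enumerate all frame pairs, drop pairs failing the motion recommendations,
#' match border points, triangulate, fit an ellipse and measure per pair, and
#' pool the per-pair estimates with quartile-based outlier rejection.
#'
#' @param frames list of frames; each a list with `pose` ([camera_pose()]) and
#'   either `mask` ([segmentation_mask()]) or a precomputed `contour`
#'   ([border_contour()], takes precedence).
#' @param rig a [rig_config()].
#' @param landmark length-3 landmark position (mm, tracker frame).
#' @param n_samples border samples used for matching.
#' @param correspondence `"shape_context"` (default) or `"exact"`
#'   (index-paired contours from the simulator).
#' @param thresholds [motion_thresholds()].
#' @param iqr_k Tukey fence multiplier for pair pooling.
#' @param residual_cap_mm per-point triangulation residual cap.
#' @param min_epipolar_sin conditioning filter for shape-context matches, see
#'   [reconstruct_border()].
#' @param min_consistency pairs whose raw assignment agrees with the dominant
#'   cyclic shift on less than this fraction of points are dropped as
#'   `inconsistent_matching` (see [refine_cyclic()]).
#' @param max_rel_fit_error pairs whose ellipse-fit RMS error exceeds this
#'   fraction of the estimated major axis are dropped as `poor_ellipse_fit`
#'   (a planar ellipse should describe the reconstructed border).
#' @param refine list of arguments passed to [refine_mask()] for mask frames.
#' @param sc list of shape-context parameters (`n_r`, `n_theta`, `r_inner`,
#'   `r_outer`).
#' @return A `polyp_measurement` with per-pair table, outlier flags, final
#'   size/location, and per-pair quality diagnostics (`pair_reports`).
#' @export
measure_polyp <- function(frames, rig, landmark,
                          n_samples = 100,
                          correspondence = c("shape_context", "exact"),
                          thresholds = motion_thresholds(),
                          iqr_k = 1.5,
                          residual_cap_mm = 2,
                          min_epipolar_sin = 0.35,
                          min_consistency = 0.6,
                          max_rel_fit_error = 0.1,
                          refine = list(),
                          sc = list()) {
  correspondence <- match.arg(correspondence)
  stopifnot(length(frames) >= 2)
  sc_par <- utils::modifyList(
    list(n_r = 5, n_theta = 12, r_inner = 0.125, r_outer = 2.0), sc)
  contours <- lapply(frames, function(fr) {
    if (!is.null(fr$contour)) return(fr$contour)
    m <- do.call(refine_mask, c(list(mask = fr$mask), refine))
    extract_border(m)
  })
  poses <- lapply(frames, function(fr) fr$pose)
  nf <- length(frames)
  pair_idx <- utils::combn(nf, 2)
  reports <- list(); estimates <- list(); skipped <- character(0)
  for (j in seq_len(ncol(pair_idx))) {
    i1 <- pair_idx[1, j]; i2 <- pair_idx[2, j]
    rep_j <- check_pair(poses[[i1]], poses[[i2]], thresholds, rig)
    pair_name <- sprintf("(%s,%s)", poses[[i1]]$frame_id, poses[[i2]]$frame_id)
    reports[[pair_name]] <- rep_j
    if (!rep_j$passed) {
      skipped <- c(skipped, sprintf("%s: %s", pair_name,
                                    paste(rep_j$failed_rules, collapse = ", ")))
      next
    }
    est <- tryCatch({
      if (correspondence == "exact") {
        corr <- exact_correspondences(contours[[i1]], contours[[i2]])
        epi_filter <- 0
      } else {
        corr <- match_shapes(contours[[i1]], contours[[i2]],
                             n_samples = n_samples,
                             n_r = sc_par$n_r, n_theta = sc_par$n_theta,
                             r_inner = sc_par$r_inner,
                             r_outer = sc_par$r_outer)
        corr <- refine_cyclic(corr)
        if (corr$consistency < min_consistency)
          stop(sprintf("inconsistent_matching (consistency %.2f)",
                       corr$consistency))
        epi_filter <- min_epipolar_sin
      }
      b3 <- reconstruct_border(corr, poses[[i1]], poses[[i2]], rig,
                               residual_cap_mm = residual_cap_mm,
                               min_epipolar_sin = epi_filter,
                               thresholds = thresholds,
                               override_motion_check = TRUE)
      fit <- fit_ellipse_3d(b3)
      if (correspondence != "exact" &&
          fit$rms_fit_error_mm > max_rel_fit_error * fit$major_axis_mm)
        stop(sprintf("poor_ellipse_fit (RMS %.2f mm on %.1f mm axis)",
                     fit$rms_fit_error_mm, fit$major_axis_mm))
      list(pair = pair_name,
           size_mm = fit$major_axis_mm,
           centre = fit$centre,
           location_mm = landmark_distance(fit, landmark),
           median_residual_mm = stats::median(b3$residuals_mm),
           n_points = nrow(b3$points),
           rms_fit_error_mm = fit$rms_fit_error_mm)
    }, error = function(e) {
      skipped <<- c(skipped, sprintf("%s: %s", pair_name, conditionMessage(e)))
      NULL
    })
    if (!is.null(est)) estimates[[length(estimates) + 1]] <- est
  }
  if (length(estimates) == 0)
    stop(paste0("no valid image pair survived quality gating:\n  ",
                paste(skipped, collapse = "\n  ")))
  out <- aggregate_pairs(estimates, iqr_k = iqr_k)
  out$per_pair <- data.frame(
    pair = vapply(estimates, `[[`, "", "pair"),
    size_mm = vapply(estimates, `[[`, 0, "size_mm"),
    location_mm = vapply(estimates, `[[`, 0, "location_mm"),
    median_residual_mm = vapply(estimates, `[[`, 0, "median_residual_mm"),
    n_points = vapply(estimates, `[[`, 0, "n_points"),
    rms_fit_error_mm = vapply(estimates, `[[`, 0, "rms_fit_error_mm"),
    outlier = out$outlier_flags)
  out$pair_reports <- reports
  out$skipped <- skipped
  out
}

#' @export
print.polyp_measurement <- function(x, ...) {
  cat(sprintf(
    "Polyp measurement: size %.2f mm, landmark distance %.2f mm (%d/%d pairs used)\n",
    x$final_size_mm, x$final_location_mm, x$n_pairs_used,
    length(x$outlier_flags)))
  invisible(x)
}
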
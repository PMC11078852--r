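test_that("noiseless borders triangulate onto the ground-truth curve", {
  r <- noiseless_scene()
  corr <- exact_correspondences(r$contours[[1]], r$contours[[2]])
  b3 <- reconstruct_border(corr, r$true_poses[[1]], r$true_poses[[2]], r$rig)
  expect_true(all(b3$residuals_mm < 1e-6))
  # points land back on the generating border curve
  truth <- make_polyp(12, 7, centre = c(15, -10, 70),
                      normal = unit_vec(c(0.2, -0.1, 1)),
                      theta_deg = 35)$border3d
  expect_lt(max(abs(b3$points - truth)), 1e-6)
})

test_that("pairs failing the motion gate are rejected unless overridden", {
  r <- noiseless_scene(n_views = 2)
  corr <- exact_correspondences(r$contours[[1]], r$contours[[2]])
  strict <- motion_thresholds(min_translation_mm = 29, max_translation_mm = 30)
  expect_error(reconstruct_border(corr, r$true_poses[[1]], r$true_poses[[2]],
                                  r$rig, thresholds = strict),
               "minimal_movement")
  b3 <- reconstruct_border(corr, r$true_poses[[1]], r$true_poses[[2]], r$rig,
                           thresholds = strict, override_motion_check = TRUE)
  expect_true(all(b3$residuals_mm < 1e-6)) # override skips the gate only
})

test_that("ellipse fitting recovers constructed 3D ellipses exactly", {
  # 40 points on a 12 x 7 mm ellipse in an arbitrary plane
  t <- seq(0, 2 * pi, length.out = 41)[-41]
  R <- quat_to_rotmat(quat_from_axis_angle(c(1, -2, 0.5), 37))
  pts <- t(R %*% rbind(6 * cos(t), 3.5 * sin(t), 0)) +
    matrix(c(30, -12, 95), 40, 3, byrow = TRUE)
  fit <- fit_ellipse_3d(pts)
  expect_equal(fit$major_axis_mm, 12, tolerance = 1e-6)
  expect_equal(fit$minor_axis_mm, 7, tolerance = 1e-6)
  expect_equal(fit$centre, c(30, -12, 95), tolerance = 1e-6)
  expect_lt(fit$rms_fit_error_mm, 1e-9)
  expect_lt(abs(sum(fit$normal * fit$major_direction)), 1e-9)
  expect_gte(fit$major_axis_mm, fit$minor_axis_mm)

  # circle of diameter 10: both axes equal 10
  circ <- t(R %*% rbind(5 * cos(t), 5 * sin(t), 0))
  fc <- fit_ellipse_3d(circ)
  expect_equal(fc$major_axis_mm, 10, tolerance = 1e-6)
  expect_equal(fc$minor_axis_mm, 10, tolerance = 1e-6)

  collinear <- cbind(seq_len(10), 2 * seq_len(10), 3 * seq_len(10))
  expect_error(fit_ellipse_3d(collinear), "collinear")
})

test_that("landmark distance is Euclidean and rigid-invariant", {
  t <- seq(0, 2 * pi, length.out = 21)[-21]
  pts <- cbind(6 * cos(t), 3.5 * sin(t), 0)
  fit <- fit_ellipse_3d(pts)
  expect_equal(landmark_distance(fit, fit$centre), 0)
  expect_equal(landmark_distance(c(0, 0, 0), c(3, 4, 0)), 5)

  set.seed(41)
  for (i in 1:10) {
    Rg <- quat_to_rotmat(random_quat()); tg <- runif(3, -100, 100)
    lm <- runif(3, -50, 50)
    d0 <- landmark_distance(fit, lm)
    fit_g <- fit_ellipse_3d(t(Rg %*% t(pts)) +
                              matrix(tg, nrow(pts), 3, byrow = TRUE))
    d1 <- landmark_distance(fit_g, as.numeric(Rg %*% lm + tg))
    expect_equal(d0, d1, tolerance = 1e-9)
  }
})

test_that("quartile outlier rejection matches an independent oracle", {
  est <- function(size, centre, loc = 100)
    list(size_mm = size, centre = centre, location_mm = loc)

  # five identical estimates: no outliers, final equals the common value
  same <- replicate(5, est(9, c(1, 2, 3)), simplify = FALSE)
  a0 <- aggregate_pairs(same)
  expect_false(any(a0$outlier_flags))
  expect_equal(a0$final_size_mm, 9)

  # nine clustered centres plus one 50 mm away: exactly that one flagged
  set.seed(42)
  ests <- lapply(1:9, function(i) est(10 + rnorm(1, 0, 0.1),
                                      c(5, 5, 5) + runif(3, -0.25, 0.25)))
  ests[[10]] <- est(25, c(55, 5, 5))
  agg <- aggregate_pairs(ests)
  expect_equal(which(agg$outlier_flags), 10L)

  # the fence agrees with a from-scratch type-7 quartile computation
  centres <- do.call(rbind, lapply(ests, `[[`, "centre"))
  med <- apply(centres, 2, median)
  d <- sqrt(rowSums(sweep(centres, 2, med)^2))
  q1 <- quartile_oracle(d, 0.25); q3 <- quartile_oracle(d, 0.75)
  expect_equal(which(d > q3 + 1.5 * (q3 - q1)), which(agg$outlier_flags))

  # single estimate passes through
  a1 <- aggregate_pairs(list(est(7, c(0, 0, 0), 42)))
  expect_equal(a1$final_size_mm, 7)
  expect_equal(a1$n_pairs_used, 1L)
  expect_false(any(a1$outlier_flags))

  # all-inlier input reduces to the plain mean
  sizes <- vapply(ests[1:9], `[[`, 0, "size_mm")
  a2 <- aggregate_pairs(ests[1:9])
  expect_equal(a2$final_size_mm, mean(sizes))

  expect_error(aggregate_pairs(list()), "no estimates")
})

test_that("end-to-end measurement is exact on noiseless scenes", {
  r <- noiseless_scene(major = 12, minor = 7)
  frames <- Map(function(ct, p) list(contour = ct, pose = p),
                r$contours, r$true_poses)
  m <- measure_polyp(frames, r$rig, r$landmark, correspondence = "exact")
  expect_equal(m$final_size_mm, 12, tolerance = 1e-3)
  expect_equal(m$final_location_mm, r$truth$location_mm, tolerance = 1e-3)

  # two frames: exactly one usable pair
  m2 <- measure_polyp(frames[1:2], r$rig, r$landmark, correspondence = "exact")
  expect_equal(nrow(m2$per_pair), 1L)
  expect_equal(m2$n_pairs_used, 1L)
})

test_that("a cluster of near-identical poses cannot be measured", {
  r <- noiseless_scene(n_views = 2)
  base <- r$true_poses[[1]]
  frames <- lapply(1:5, function(i)
    list(contour = r$contours[[1]],
         pose = camera_pose(base$position + runif(3, -0.25, 0.25),
                            base$quaternion, frame_id = paste0("p", i))))
  err <- tryCatch(measure_polyp(frames, r$rig, r$landmark),
                  error = function(e) conditionMessage(e))
  expect_match(err, "no valid image pair")
  expect_match(err, "minimal_movement")
})

test_that("rigid transforms leave size and location estimates unchanged", {
  r <- noiseless_scene()
  frames <- Map(function(ct, p) list(contour = ct, pose = p),
                r$contours, r$true_poses)
  m0 <- measure_polyp(frames, r$rig, r$landmark, correspondence = "exact")

  set.seed(43)
  Rg <- quat_to_rotmat(random_quat()); tg <- runif(3, -200, 200)
  frames_g <- lapply(frames, function(fr) {
    p <- fr$pose
    list(contour = fr$contour,
         pose = camera_pose(as.numeric(Rg %*% p$position + tg),
                            rotmat_to_quat(Rg %*% quat_to_rotmat(p$quaternion)),
                            frame_id = p$frame_id))
  })
  m1 <- measure_polyp(frames_g, r$rig, as.numeric(Rg %*% r$landmark + tg),
                      correspondence = "exact")
  expect_equal(m1$final_size_mm, m0$final_size_mm, tolerance = 1e-6)
  expect_equal(m1$final_location_mm, m0$final_location_mm, tolerance = 1e-6)
})
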
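test_that("projection obeys the pinhole model", {
  rig <- test_rig()
  pose <- camera_pose(c(0, 0, 0), c(1, 0, 0, 0), frame_id = "a")
  # optical axis maps to the principal point at any depth
  expect_equal(as.numeric(project_points(c(0, 0, 57), pose, rig)),
               c(250, 250))
  # similar triangles: fx * X / Z + cx
  expect_equal(as.numeric(project_points(c(10, 0, 100), pose, rig)),
               c(500 * 10 / 100 + 250, 250))
  expect_error(project_points(c(0, 0, -5), pose, rig), "behind camera")
  expect_error(project_points(c(1, 1, 0), pose, rig), "behind camera")
})

test_that("back-projection is the inverse of projection up to depth", {
  rig <- test_rig()
  pose <- camera_pose(c(0, 0, 0), c(1, 0, 0, 0))
  r0 <- backproject_ray(c(250, 250), pose, rig)
  expect_equal(r0$direction, c(0, 0, 1), tolerance = 1e-12)
  # one focal length off-centre corresponds to a 45-degree ray
  r45 <- backproject_ray(c(250 + 500, 250), pose, rig)
  expect_equal(r45$direction, c(1, 0, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(101)
  for (i in 1:300) {
    p <- random_pose()
    ray_dir <- unit_vec(quat_to_rotmat(p$quaternion)[, 3] + rnorm(3, 0, 0.2))
    X <- p$position + runif(1, 30, 150) * ray_dir
    uv <- tryCatch(project_points(X, p, rig), error = function(e) NULL)
    if (is.null(uv)) next
    ray <- backproject_ray(as.numeric(uv), p, rig)
    v <- X - ray$origin
    dist_to_ray <- sqrt(sum((v - sum(v * ray$direction) * ray$direction)^2))
    expect_lt(dist_to_ray, 1e-6)
  }
})

test_that("distorted projection round-trips through iterative undistortion", {
  rig <- test_rig(distortion = c(-0.2, 0.05, 0, 1e-3, -5e-4))
  pose <- camera_pose(c(5, -3, 10), random_quat_fixed <- c(1, 0, 0, 0))
  set.seed(7)
  for (i in 1:50) {
    X <- pose$position + c(runif(2, -20, 20), runif(1, 40, 120))
    uv <- project_points(X, pose, rig)
    ray <- backproject_ray(as.numeric(uv), pose, rig)
    v <- X - ray$origin
    dist_to_ray <- sqrt(sum((v - sum(v * ray$direction) * ray$direction)^2))
    expect_lt(dist_to_ray, 1e-6)
  }
})

test_that("projection is invariant under a global rigid transform", {
  rig <- test_rig()
  set.seed(42)
  for (i in 1:20) {
    pose <- random_pose()
    X <- pose$position + quat_to_rotmat(pose$quaternion) %*% c(5, -2, 80)
    Rg <- quat_to_rotmat(random_quat())
    tg <- runif(3, -50, 50)
    pose_g <- camera_pose(as.numeric(Rg %*% pose$position + tg),
                          rotmat_to_quat(Rg %*% quat_to_rotmat(pose$quaternion)))
    Xg <- as.numeric(Rg %*% X + tg)
    expect_equal(project_points(as.numeric(X), pose, rig),
                 project_points(Xg, pose_g, rig), tolerance = 1e-8)
  }
})

test_that("relative motion reports translation, rotation and axis angle", {
  p0 <- camera_pose(c(0, 0, 0), c(1, 0, 0, 0))
  m0 <- relative_motion(p0, p0)
  expect_equal(m0$translation_mm, 0)
  expect_equal(m0$rotation_deg, 0)
  expect_equal(m0$translation_axis_angle_deg, 0) # convention for no motion

  # pure 10 mm forward translation along the shared optical axis (+z)
  p1 <- camera_pose(c(0, 0, 10), c(1, 0, 0, 0))
  m1 <- relative_motion(p0, p1)
  expect_equal(m1$translation_mm, 10)
  expect_equal(m1$rotation_deg, 0)
  expect_equal(m1$translation_axis_angle_deg, 0)

  # a 30-degree rotation about an arbitrary axis, no translation
  q30 <- quat_from_axis_angle(c(1, 2, -0.5), 30)
  m2 <- relative_motion(p0, camera_pose(c(0, 0, 0), q30))
  expect_equal(m2$rotation_deg, 30, tolerance = 1e-9)

  # scalar outputs are symmetric in the two poses
  set.seed(3)
  for (i in 1:20) {
    a <- random_pose(); b <- random_pose()
    mab <- relative_motion(a, b); mba <- relative_motion(b, a)
    expect_equal(mab$translation_mm, mba$translation_mm)
    expect_equal(mab$rotation_deg, mba$rotation_deg)
    expect_equal(mab$translation_axis_angle_deg,
                 mba$translation_axis_angle_deg, tolerance = 1e-9)
  }
})

test_that("triangulation recovers ray intersections and flags degeneracy", {
  ray <- function(o, d) structure(list(origin = o, direction = unit_vec(d)),
                                  class = "ray")
  # two rays through a common point
  tr <- triangulate_pair(ray(c(1, 2, 3) - 5 * c(1, 0, 0), c(1, 0, 0)),
                         ray(c(1, 2, 3) - 7 * c(0, 1, 0.5), c(0, 1, 0.5)))
  expect_equal(tr$point3d, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(tr$residual_mm, 1e-9)

  # closed-form skew pair: common perpendicular midpoint and length
  tr2 <- triangulate_pair(ray(c(0, 0, 0), c(0, 0, 1)),
                          ray(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(tr2$point3d, c(0.5, 0, 0))
  expect_equal(tr2$residual_mm, 1)

  expect_error(triangulate_pair(ray(c(0, 0, 0), c(0, 0, 1)),
                                ray(c(5, 0, 0), c(0, 0, 1))),
               "degenerate")

  # property: rays constructed through a common point triangulate exactly,
  # and the vectorized bundle path agrees with the scalar path
  set.seed(12)
  for (i in 1:50) {
    X <- runif(3, -50, 50)
    o1 <- X + runif(1, 20, 60) * unit_vec(rnorm(3))
    o2 <- X + runif(1, 20, 60) * unit_vec(rnorm(3))
    tr3 <- triangulate_pair(ray(o1, X - o1), ray(o2, X - o2))
    expect_equal(tr3$point3d, X, tolerance = 1e-9)
    expect_lt(tr3$residual_mm, 1e-9)
  }
})

test_that("hand-eye transform relocates the camera relative to the sensor", {
  K <- camera_intrinsics(500, 500, 250, 250, 500, 500)
  he_R <- quat_to_rotmat(quat_from_axis_angle(c(0, 1, 0), 12))
  he_t <- c(4, -2, 9)
  rig <- rig_config(K, hand_eye_rotation = he_R, hand_eye_translation = he_t)
  pose <- random_pose()
  # camera centre must map to the sensor-frame offset implied by the hand-eye
  ray <- backproject_ray(c(250, 250), pose, rig)
  R_ws <- quat_to_rotmat(pose$quaternion)
  expected_centre <- pose$position - as.numeric(R_ws %*% t(he_R) %*% he_t)
  expect_equal(ray$origin, expected_centre, tolerance = 1e-9)
  # projection still inverts with the offset rig
  X <- ray$origin + 75 * ray$direction
  expect_equal(as.numeric(project_points(X, pose, rig)), c(250, 250),
               tolerance = 1e-7)
})
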
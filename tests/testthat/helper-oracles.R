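# Independent oracles and fixture builders used across the suite.

# Random unit quaternion / pose generators (uniform rotation via normalized
# Gaussian quaternion).
random_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

random_pose <- function(scale = 100) {
  camera_pose(runif(3, -scale, scale), random_quat(),
              frame_id = sprintf("r%04d", sample.int(9999, 1)))
}

test_rig <- function(fx = 500, fy = 500, cx = 250, cy = 250, w = 500, h = 500,
                     distortion = numeric(0)) {
  rig_config(camera_intrinsics(fx, fy, cx, cy, w, h, distortion))
}

# Brute-force chi-squared histogram distance on normalized counts.
chi2_brute <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sum(a) > 0) a <- a / sum(a)
  if (sum(b) > 0) b <- b / sum(b)
  total <- 0
  for (i in seq_along(a)) {
    s <- a[i] + b[i]
    if (s > 0) total <- total + (a[i] - b[i])^2 / s
  }
  total / 2
}

# All permutations of 1:n (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Type-7 quartile computed from first principles (sort + linear interpolation).
quartile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Two-way ANOVA mean squares via stats::aov (independent route from the
# package's direct sums-of-squares computation).
icc_aov_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  MSR <- tab["subject", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Rasterized shapes for contour tests.
disc_mask <- function(r, cx, cy, w, h) {
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), w), nrow = h)
  segmentation_mask(((xs - cx)^2 + (ys - cy)^2) <= r^2, frame_id = "disc")
}

rect_mask <- function(x0, y0, x1, y1, w, h) {
  px <- matrix(0L, h, w)
  px[(y0:y1) + 1, (x0:x1) + 1] <- 1L
  segmentation_mask(px, frame_id = "rect")
}

ellipse_mask <- function(a, b, cx, cy, w, h) {
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), w), nrow = h)
  segmentation_mask(((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1,
                    frame_id = "ellipse")
}

circle_contour <- function(r = 50, n = 3600, cx = 0, cy = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  border_contour(cbind(cx + r * cos(t), cy + r * sin(t)), frame_id = "circle")
}

# An asymmetric simple polygon with distinct local geometry at each vertex.
asymmetric_polygon <- function() {
  rbind(c(0, 0), c(4, 0.5), c(6, 3), c(5, 6), c(2.5, 7), c(0.5, 5), c(-1, 2))
}

polygon_perimeter <- function(pts) {
  p2 <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(p2)^2)))
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

hausdorff_distance <- function(a, b) {
  dd <- as.matrix(stats::dist(rbind(a, b)))
  na <- nrow(a)
  cross <- dd[seq_len(na), -seq_len(na), drop = FALSE]
  max(max(apply(cross, 1, min)), max(apply(cross, 2, min)))
}

# Noiseless rendered scene used by several end-to-end tests.
noiseless_scene <- function(major = 12, minor = 7, n_views = 5, seed = 11) {
  polyp <- make_polyp(major, minor, centre = c(15, -10, 70),
                      normal = unit_vec(c(0.2, -0.1, 1)), theta_deg = 35)
  poses <- make_pose_set(polyp, n_views = n_views, seed = seed)
  scene <- synthetic_scene(polyp, poses, landmark = c(0, 0, 250),
                           pose_pos_sigma_mm = 0, pose_rot_sigma_deg = 0,
                           pixel_sigma_px = 0, seed = seed + 1)
  render_views(scene)
}

unit_vec <- function(v) v / sqrt(sum(v^2))
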
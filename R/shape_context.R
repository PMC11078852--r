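#' Shape-context descriptor of one border point
#'
#' A log-polar histogram of the positions of all other points of the shape,
#' measured from a reference point. Radii are normalized by the mean pairwise
#' distance of the full point set (scale invariance); angles are measured in
#' the image frame (x-axis = 0, counter-clockwise positive), i.e. descriptors
#' are deliberately not rotation-normalized: usable view pairs are constrained
#' to small relative rotations, so image-frame orientation is signal.
#'
#' @param points nx2 matrix of 2D points.
#' @param ref_index index (1-based) of the reference point.
#' @param n_r radial bin count (>= 1); default 5.
#' @param n_theta angular bin count (>= 2); default 12.
#' @param r_inner,r_outer radial range as fractions of the mean pairwise
#'   distance; points outside the range are dropped from the histogram.
#' @param mean_dist optionally precomputed mean pairwise distance.
#' @return An object of class `shape_context` with the count histogram
#'   (`n_r` x `n_theta`) and the bin geometry.
#' @export
compute_descriptor <- function(points, ref_index, n_r = 5, n_theta = 12,
                               r_inner = 0.125, r_outer = 2.0,
                               mean_dist = NULL) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 2) stop("shape context needs at least 2 points")
  stopifnot(ref_index >= 1, ref_index <= n, n_r >= 1, n_theta >= 2,
            r_inner > 0, r_outer > r_inner)
  if (is.null(mean_dist)) mean_dist <- mean(stats::dist(pts))
  rel <- sweep(pts[-ref_index, , drop = FALSE], 2, pts[ref_index, ])
  r <- sqrt(rowSums(rel^2)) / mean_dist
  theta <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  r_edges <- exp(seq(log(r_inner), log(r_outer), length.out = n_r + 1))
  hist <- matrix(0L, nrow = n_r, ncol = n_theta)
  keep <- r >= r_inner & r <= r_outer
  if (any(keep)) {
    ri <- findInterval(r[keep], r_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ti <- pmin(floor(theta[keep] / (2 * pi / n_theta)) + 1, n_theta)
    for (k in seq_along(ri)) hist[ri[k], ti[k]] <- hist[ri[k], ti[k]] + 1L
  }
  structure(list(histogram = hist, ref_index = ref_index,
                 n_r = n_r, n_theta = n_theta,
                 r_inner = r_inner, r_outer = r_outer),
            class = "shape_context")
}

#' Chi-squared distance between two shape-context descriptors
#'
#' Histograms are normalized to unit mass, then compared with the chi-squared
#' statistic `0.5 * sum((a - b)^2 / (a + b))`, with empty-empty bins
#' contributing 0. Symmetric; 0 iff the normalized histograms are identical.
#'
#' @param h_p,h_q `shape_context` descriptors with identical bin geometry.
#' @return scalar cost in `[0, 1]`.
#' @export
descriptor_cost <- function(h_p, h_q) {
  stopifnot(inherits(h_p, "shape_context"), inherits(h_q, "shape_context"))
  if (h_p$n_r != h_q$n_r || h_p$n_theta != h_q$n_theta)
    stop("descriptors have mismatched bin shapes")
  a <- as.numeric(h_p$histogram); b <- as.numeric(h_q$histogram)
  if (sum(a) > 0) a <- a / sum(a)
  if (sum(b) > 0) b <- b / sum(b)
  chi2_cost(a, b)
}

chi2_cost <- function(a, b) {
  s <- a + b
  d <- (a - b)^2
  ok <- s > 0
  0.5 * sum(d[ok] / s[ok])
}

# All descriptors of one point set as a matrix (n x n_r*n_theta), rows
# normalized to unit mass.
descriptor_matrix <- function(pts, n_r, n_theta, r_inner, r_outer) {
  n <- nrow(pts)
  md <- mean(stats::dist(pts))
  out <- matrix(0, nrow = n, ncol = n_r * n_theta)
  for (i in seq_len(n)) {
    h <- compute_descriptor(pts, i, n_r, n_theta, r_inner, r_outer,
                            mean_dist = md)$histogram
    v <- as.numeric(h)
    if (sum(v) > 0) v <- v / sum(v)
    out[i, ] <- v
  }
  out
}

#' Match two border contours by shape context
#'
#' Both contours are resampled to `n_samples` points, per-point shape-context
#' descriptors are computed, and the one-to-one correspondence minimizing the
#' total chi-squared cost is solved exactly (optimal linear sum assignment).
#'
#' @param P,Q [border_contour()] objects (or nx2 point matrices).
#' @param n_samples number of border samples used for matching (>= 3).
#' @param n_r,n_theta,r_inner,r_outer shape-context bin geometry, see
#'   [compute_descriptor()].
#' @param resample set `FALSE` to match the given points as-is.
#' @return An object of class `correspondence_set`: `pairs` (two-column matrix
#'   of indices into P and Q, sorted by the P index), `total_cost`,
#'   `per_pair_cost`, and the matched coordinates `points_p`, `points_q`.
#' @export
match_shapes <- function(P, Q, n_samples = 100, n_r = 5, n_theta = 12,
                         r_inner = 0.125, r_outer = 2.0, resample = TRUE) {
  stopifnot(n_samples >= 3)
  get_pts <- function(X) {
    if (inherits(X, "border_contour")) {
      if (resample) resample_contour(X, n_samples)$points else X$points
    } else as.matrix(X)
  }
  p <- get_pts(P); q <- get_pts(Q)
  A <- descriptor_matrix(p, n_r, n_theta, r_inner, r_outer)
  B <- descriptor_matrix(q, n_r, n_theta, r_inner, r_outer)
  cost <- sc_cost_matrix(A, B)
  if (nrow(p) <= ncol(cost)) {
    sol <- clue::solve_LSAP(cost)
    pairs <- cbind(seq_len(nrow(p)), as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(cost))
    pairs <- cbind(as.integer(sol), seq_len(nrow(q)))
  }
  per_cost <- cost[pairs]
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  per_cost <- per_cost[ord]
  correspondence_set(pairs, per_cost, p, q, cost_matrix = cost)
}

correspondence_set <- function(pairs, per_pair_cost, points_p, points_q,
                               cost_matrix = NULL) {
  colnames(pairs) <- c("index_p", "index_q")
  structure(list(pairs = pairs,
                 total_cost = sum(per_pair_cost),
                 per_pair_cost = per_pair_cost,
                 points_p = points_p, points_q = points_q,
                 cost_matrix = cost_matrix),
            class = "correspondence_set")
}

#' Cyclic-order refinement of a closed-contour correspondence
#'
#' Two uniformly resampled closed contours of the same physical border are
#' related, up to perspective, by an order-preserving cyclic shift of the
#' sample index. The raw optimal assignment can contain order-violating
#' matches (for smooth, near-circular borders many assignments have nearly
#' equal shape-context cost, and order reversals reconstruct a phantom,
#' inflated border). This step extracts the dominant cyclic shift from the
#' assignment, measures how consistent the assignment is with it, re-pairs
#' every point at that shift, and snaps each match within a small window to
#' the cheapest bin of the stored cost matrix.
#'
#' @param corr a `correspondence_set` from [match_shapes()] on two contours
#'   with equal sample counts.
#' @param window half-width (in samples) of the per-point snap around the
#'   dominant shift; 0 disables snapping.
#' @param consistency_tol matches within this many samples of the dominant
#'   shift (circularly) count as consistent.
#' @return A `correspondence_set` with fields `shift` (the dominant cyclic
#'   shift) and `consistency` (fraction of raw matches consistent with it).
#' @export
refine_cyclic <- function(corr, window = 2, consistency_tol = 3) {
  stopifnot(inherits(corr, "correspondence_set"))
  n <- nrow(corr$points_p)
  if (nrow(corr$points_q) != n)
    stop("cyclic refinement requires contours with equal sample counts")
  shifts <- (corr$pairs[, 2] - corr$pairs[, 1]) %% n
  tab <- tabulate(shifts + 1, nbins = n)
  k <- which.max(tab) - 1
  d <- pmin((shifts - k) %% n, (k - shifts) %% n)
  consistency <- mean(d <= consistency_tol)
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  C <- corr$cost_matrix
  if (!is.null(C) && window > 0) {
    idx <- vapply(seq_len(n), function(i) {
      cand <- ((i - 1 + k + (-window:window)) %% n) + 1
      cand[which.min(C[i, cand])]
    }, numeric(1))
  }
  per_cost <- if (!is.null(C)) C[cbind(seq_len(n), idx)] else rep(0, n)
  out <- correspondence_set(cbind(seq_len(n), idx), per_cost,
                            corr$points_p, corr$points_q, cost_matrix = C)
  out$shift <- k
  out$consistency <- consistency
  out
}

# Chi-squared cost matrix between row-normalized descriptor matrices.
sc_cost_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  cost <- matrix(0, n, m)
  for (k in seq_len(ncol(A))) {
    s <- outer(A[, k], B[, k], "+")
    d <- outer(A[, k], B[, k], "-")^2
    ok <- s > 0
    d[ok] <- d[ok] / s[ok]
    d[!ok] <- 0
    cost <- cost + d
  }
  0.5 * cost
}

#' Exact index-paired correspondences
#'
#' Pairs point i of P with point i of Q, for simulator outputs whose contours
#' share ground-truth indexing; isolates the reconstruction geometry from the
#' matching step.
#'
#' @param P,Q [border_contour()] objects or nx2 matrices with equal row counts.
#' @return A `correspondence_set` with zero costs.
#' @export
exact_correspondences <- function(P, Q) {
  p <- if (inherits(P, "border_contour")) P$points else as.matrix(P)
  q <- if (inherits(Q, "border_contour")) Q$points else as.matrix(Q)
  if (nrow(p) != nrow(q))
    stop("exact correspondence requires contours with equal point counts")
  n <- nrow(p)
  correspondence_set(cbind(seq_len(n), seq_len(n)), rep(0, n), p, q)
}
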
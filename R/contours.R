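#' Segmentation mask
#'
#' A binary mask stored as a logical/integer matrix indexed `[y + 1, x + 1]`
#' for the 0-based pixel (x, y): rows run down the image, columns across.
#'
#' @param pixels matrix (height x width), nonzero = foreground.
#' @param frame_id identifier of the source frame.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, frame_id = NA_character_) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = matrix(as.integer(pixels != 0), nrow = nrow(pixels)),
                 frame_id = as.character(frame_id)),
            class = "segmentation_mask")
}

#' Ordered border contour
#'
#' @param points nx2 matrix of (x, y) pixel coordinates (sub-pixel allowed).
#' @param closed logical; closed contours do not repeat their first vertex.
#' @param frame_id identifier of the source frame.
#' @return An object of class `border_contour`.
#' @export
border_contour <- function(points, closed = TRUE, frame_id = NA_character_) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 3, all(is.finite(pts)))
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, closed = isTRUE(closed),
                 frame_id = as.character(frame_id)),
            class = "border_contour")
}

# Signed area (shoelace) in stored (x, y) coordinates. Positive is the
# package's canonical counter-clockwise orientation in the image frame.
contour_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

contour_arc_lengths <- function(pts, closed = TRUE) {
  p2 <- if (closed) rbind(pts, pts[1, , drop = FALSE]) else pts
  sqrt(rowSums(diff(p2)^2))
}

ebimg <- function(pixels) EBImage::Image(t(pixels))

mask_components <- function(pixels) {
  lab <- EBImage::bwlabel(ebimg(pixels))
  t(EBImage::imageData(lab))
}

#' Refine a segmentation mask
#'
#' Post-processing of a raw polyp segmentation: morphological opening, removal
#' of small connected components, interior hole filling, and an optional
#' region-based active-contour refinement of the largest component against a
#' grayscale frame (for outputs that cover the polyp only partially). Exactly
#' one connected component (the largest) remains.
#'
#' @param mask a [segmentation_mask()].
#' @param min_region_px components smaller than this many pixels are removed.
#' @param fill_holes fill interior holes.
#' @param active_contour refine the boundary with a Chan-Vese-style
#'   region-based deformable model; requires `image`.
#' @param image optional grayscale matrix (same size as the mask) used by the
#'   active contour.
#' @param opening_radius structuring-element (disc) radius in pixels.
#' @param ac_iter iteration cap for the active contour.
#' @return A refined [segmentation_mask()].
#' @export
refine_mask <- function(mask, min_region_px = 100, fill_holes = TRUE,
                        active_contour = FALSE, image = NULL,
                        opening_radius = 2, ac_iter = 200) {
  stopifnot(inherits(mask, "segmentation_mask"))
  px <- mask$pixels
  if (sum(px) == 0) stop("empty after refinement: mask has no foreground")
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    px <- t(EBImage::imageData(EBImage::opening(ebimg(px), brush)))
  }
  lab <- mask_components(px)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_region_px)
  if (length(keep) == 0)
    stop("empty after refinement: all components below min_region_px")
  largest <- keep[which.max(sizes[keep])]
  px <- matrix(as.integer(lab == largest), nrow = nrow(px))
  if (fill_holes)
    px <- t(EBImage::imageData(EBImage::fillHull(ebimg(px))))
  if (active_contour) {
    if (is.null(image)) stop("active_contour = TRUE requires a grayscale image")
    px <- active_contour_refine(px, image, max_iter = ac_iter)
    lab <- mask_components(px)
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes) == 0) stop("empty after refinement: active contour collapsed")
    px <- matrix(as.integer(lab == which.max(sizes)), nrow = nrow(px))
    if (fill_holes)
      px <- t(EBImage::imageData(EBImage::fillHull(ebimg(px))))
  }
  segmentation_mask(px, frame_id = mask$frame_id)
}

# Morphological Chan-Vese-style two-phase segmentation, initialised from the
# given mask. Alternates the region competition update (assign each pixel to
# the closer of the inside/outside mean intensities) restricted to a narrow
# band around the current boundary with an opening-closing smoothing step.
active_contour_refine <- function(px, image, max_iter = 200, band = 3,
                                  smooth_radius = 1) {
  stopifnot(is.matrix(image), all(dim(image) == dim(px)))
  u <- px
  brush <- EBImage::makeBrush(2 * smooth_radius + 1, shape = "disc")
  band_brush <- EBImage::makeBrush(2 * band + 1, shape = "disc")
  for (i in seq_len(max_iter)) {
    inside <- u == 1
    c1 <- mean(image[inside]); c2 <- mean(image[!inside])
    if (!is.finite(c1) || !is.finite(c2)) break
    img_u <- ebimg(u)
    dil <- EBImage::imageData(EBImage::dilate(img_u, band_brush))
    ero <- EBImage::imageData(EBImage::erode(img_u, band_brush))
    in_band <- t(dil - ero) > 0
    u_new <- u
    u_new[in_band] <- as.integer((image[in_band] - c1)^2 <
                                   (image[in_band] - c2)^2)
    sm <- EBImage::opening(EBImage::closing(ebimg(u_new), brush), brush)
    u_new <- matrix(as.integer(t(EBImage::imageData(sm)) > 0), nrow = nrow(u))
    if (identical(u_new, u)) break
    u <- u_new
  }
  u
}

#' Extract the outer border of a mask
#'
#' Sub-pixel outer boundary of the single connected component, traced with
#' marching squares at the 0.5 level, ordered counter-clockwise and closed.
#'
#' @param mask a [segmentation_mask()] with exactly one connected component.
#' @return A [border_contour()].
#' @export
extract_border <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  px <- mask$pixels
  lab <- mask_components(px)
  ncomp <- max(lab)
  if (ncomp == 0) stop("mask has no foreground; run refine_mask first")
  if (ncomp > 1)
    stop(sprintf("mask has %d connected components; run refine_mask first",
                 ncomp))
  if (sum(px) < 3)
    stop("component too small: fewer than 3 boundary points")
  h <- nrow(px); w <- ncol(px)
  # A 3x3 box average turns the binary grid into local area fractions, so the
  # marching-squares 0.5 crossing interpolates the true edge at sub-pixel
  # accuracy instead of tracing the jagged pixel staircase.
  sm <- t(EBImage::imageData(EBImage::filter2(ebimg(px),
                                              matrix(1 / 9, 3, 3),
                                              boundary = 0)))
  cl <- grDevices::contourLines(x = 0:(w - 1), y = 0:(h - 1),
                                z = t(sm), levels = 0.5)
  if (length(cl) == 0) # very thin component: fall back to the binary grid
    cl <- grDevices::contourLines(x = 0:(w - 1), y = 0:(h - 1),
                                  z = t(px), levels = 0.5)
  if (length(cl) == 0) stop("no boundary found at the 0.5 level")
  polys <- lapply(cl, function(c0) cbind(c0$x, c0$y))
  areas <- vapply(polys, function(p) abs(contour_signed_area(p)), 0)
  pts <- polys[[which.max(areas)]]
  if (sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 boundary points")
  if (contour_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  border_contour(pts, closed = TRUE, frame_id = mask$frame_id)
}

#' Resample a contour uniformly by arc length
#'
#' @param contour a [border_contour()].
#' @param n_points number of output samples (>= 3), equally spaced by arc
#'   length along the closed curve, starting at the input's first vertex.
#' @return A [border_contour()] with `n_points` vertices.
#' @export
resample_contour <- function(contour, n_points) {
  stopifnot(inherits(contour, "border_contour"), n_points >= 3)
  pts <- contour$points
  closed <- contour$closed
  p2 <- if (closed) rbind(pts, pts[1, , drop = FALSE]) else pts
  seg <- sqrt(rowSums(diff(p2)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < .Machine$double.eps) stop("degenerate contour with zero length")
  targets <- if (closed) seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
             else seq(0, total, length.out = n_points)
  x <- stats::approx(s, p2[, 1], xout = targets, ties = "ordered")$y
  y <- stats::approx(s, p2[, 2], xout = targets, ties = "ordered")$y
  border_contour(cbind(x, y), closed = closed, frame_id = contour$frame_id)
}
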
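#' Read and write pose logs
#'
#' Pose log CSV columns (fixed order, version 1): `frame_id, t, x_mm, y_mm,
#' z_mm, qw, qx, qy, qz` — tracker-frame sensor position in mm and the
#' scalar-first unit quaternion rotating sensor-frame vectors into the tracker
#' frame. A `#`-prefixed header comment in written files records the
#' convention.
#'
#' @param path CSV file path.
#' @return `read_pose_log()` returns a named list of [camera_pose()] objects
#'   keyed by `frame_id`.
#' @export
read_pose_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame_id", "t", "x_mm", "y_mm", "z_mm", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed pose log %s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  poses <- lapply(seq_len(nrow(df)), function(i)
    camera_pose(c(df$x_mm[i], df$y_mm[i], df$z_mm[i]),
                c(df$qw[i], df$qx[i], df$qy[i], df$qz[i]),
                frame_id = df$frame_id[i], timestamp = df$t[i]))
  names(poses) <- df$frame_id
  poses
}

#' @rdname read_pose_log
#' @param poses list of [camera_pose()] objects.
#' @export
write_pose_log <- function(poses, path) {
  df <- do.call(rbind, lapply(poses, function(p)
    data.frame(frame_id = p$frame_id, t = p$timestamp,
               x_mm = p$position[1], y_mm = p$position[2],
               z_mm = p$position[3],
               qw = p$quaternion[1], qx = p$quaternion[2],
               qy = p$quaternion[3], qz = p$quaternion[4])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pose log v1: sensor pose in tracker frame; ",
                    "quaternion scalar-first (qw,qx,qy,qz), mm"), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rig configuration YAML
#'
#' YAML layout: an `intrinsics` block (`fx, fy, cx, cy, image_width,
#' image_height, distortion`) and a `hand_eye` block (`rotation` as three
#' 3-element rows, `translation_mm`).
#'
#' @param path YAML file path.
#' @return `read_rig_yaml()` returns a [rig_config()].
#' @export
read_rig_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$intrinsics))
    stop(sprintf("malformed rig YAML %s: missing 'intrinsics' block", path))
  ib <- y$intrinsics
  intr <- camera_intrinsics(ib$fx, ib$fy, ib$cx, ib$cy,
                            ib$image_width, ib$image_height,
                            distortion = as.numeric(unlist(ib$distortion)))
  if (is.null(y$hand_eye)) return(rig_config(intr))
  R <- do.call(rbind, lapply(y$hand_eye$rotation, as.numeric))
  # re-orthonormalize against serialization round-off; reject real corruption
  sv <- svd(R)
  R_ortho <- sv$u %*% t(sv$v)
  if (max(abs(R_ortho - R)) > 1e-6 || det(R_ortho) < 0)
    stop(sprintf("malformed rig YAML %s: hand_eye rotation is not a rotation",
                 path))
  rig_config(intr, hand_eye_rotation = R_ortho,
             hand_eye_translation = as.numeric(y$hand_eye$translation_mm))
}

#' @rdname read_rig_yaml
#' @param rig a [rig_config()].
#' @export
write_rig_yaml <- function(rig, path) {
  K <- rig$intrinsics
  y <- list(
    intrinsics = list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
                      image_width = K$image_width,
                      image_height = K$image_height,
                      distortion = as.list(K$distortion)),
    hand_eye = list(rotation = lapply(1:3, function(i)
      as.list(rig$hand_eye_rotation[i, ])),
      translation_mm = as.list(rig$hand_eye_translation)))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read and write binary masks as PNG
#'
#' Single-channel PNG, 0 = background, 255 = foreground.
#'
#' @param path PNG file path.
#' @param frame_id frame identifier attached on read.
#' @return `read_mask_png()` returns a [segmentation_mask()].
#' @export
read_mask_png <- function(path, frame_id = NA_character_) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  segmentation_mask(arr > 0.5, frame_id = frame_id)
}

#' @rdname read_mask_png
#' @param mask a [segmentation_mask()].
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

#' Write a simulated scene directory
#'
#' Writes `masks/<frame_id>.png`, `contours.csv` (noisy rendered contours),
#' `poses.csv` (noisy tracker poses), `rig.yaml`, `landmark.json` and
#' `truth.json`, the layout consumed by the `measure` CLI subcommand.
#'
#' @param rendered output of [render_views()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(rendered, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (m in rendered$masks)
    write_mask_png(m, file.path(dir, "masks", paste0(m$frame_id, ".png")))
  cdf <- do.call(rbind, lapply(rendered$contours, function(ct)
    data.frame(frame_id = ct$frame_id,
               index = seq_len(nrow(ct$points)) - 1L,
               x_px = ct$points[, 1], y_px = ct$points[, 2])))
  utils::write.csv(cdf, file.path(dir, "contours.csv"), row.names = FALSE,
                   quote = FALSE)
  write_pose_log(rendered$noisy_poses, file.path(dir, "poses.csv"))
  write_rig_yaml(rendered$rig, file.path(dir, "rig.yaml"))
  jsonlite::write_json(list(landmark_mm = rendered$landmark),
                       file.path(dir, "landmark.json"), digits = NA)
  jsonlite::write_json(rendered$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory for measurement
#'
#' @param dir directory written by [write_scene()] (or laid out the same way
#'   by hand: masks/, poses.csv, rig.yaml, landmark.json).
#' @param use_contours read `contours.csv` instead of the masks when present.
#' @return list with `frames` (list of `pose` + `mask`/`contour`), `rig`,
#'   `landmark`.
#' @export
read_scene <- function(dir, use_contours = FALSE) {
  poses <- read_pose_log(file.path(dir, "poses.csv"))
  rig <- read_rig_yaml(file.path(dir, "rig.yaml"))
  lm <- as.numeric(unlist(jsonlite::read_json(
    file.path(dir, "landmark.json"))$landmark_mm))
  contour_path <- file.path(dir, "contours.csv")
  frames <- if (use_contours && file.exists(contour_path)) {
    cdf <- utils::read.csv(contour_path, stringsAsFactors = FALSE)
    lapply(names(poses), function(fid) {
      sub <- cdf[cdf$frame_id == fid, ]
      if (nrow(sub) == 0) stop(sprintf("no contour for frame %s", fid))
      list(pose = poses[[fid]],
           contour = border_contour(cbind(sub$x_px, sub$y_px),
                                    frame_id = fid))
    })
  } else {
    mask_files <- list.files(file.path(dir, "masks"), pattern = "\\.png$",
                             full.names = TRUE)
    ids <- sub("\\.png$", "", basename(mask_files))
    missing <- setdiff(ids, names(poses))
    if (length(missing) > 0)
      stop(sprintf("pose log is missing frame(s): %s",
                   paste(missing, collapse = ", ")))
    lapply(ids, function(fid) {
      m <- read_mask_png(mask_files[ids == fid], frame_id = fid)
      K <- rig$intrinsics
      if (nrow(m$pixels) != K$image_height || ncol(m$pixels) != K$image_width)
        stop(sprintf(
          "dimension mismatch: mask %s is %dx%d but intrinsics say %dx%d",
          fid, ncol(m$pixels), nrow(m$pixels), K$image_width, K$image_height))
      list(pose = poses[[fid]], mask = m)
    })
  }
  list(frames = frames, rig = rig, landmark = lm)
}

#' Write a measurement report as JSON
#'
#' Per-pair table (sizes, locations, residual statistics, outlier flags) plus
#' the final pooled estimate.
#'
#' @param measurement a `polyp_measurement` from [measure_polyp()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(measurement, path) {
  report <- list(
    per_pair = measurement$per_pair,
    final = list(size_mm = measurement$final_size_mm,
                 location_mm = measurement$final_location_mm,
                 n_pairs_used = measurement$n_pairs_used),
    skipped_pairs = as.list(measurement$skipped))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration (as canonical JSON and its MD5), the seed, MD5
#' hashes of every input file, and the package version — enough to reproduce
#' a run exactly.
#'
#' @param path output JSON path.
#' @param config named list of run parameters.
#' @param seed integer seed used for the run.
#' @param input_files character vector of input file paths to hash.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, input_files = character(0)) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  hashes <- if (length(input_files) > 0) {
    h <- tools::md5sum(input_files)
    stats::setNames(as.list(unname(h)), basename(input_files))
  } else list()
  manifest <- list(
    package = "polypsize",
    version = as.character(utils::packageVersion("polypsize")),
    seed = seed,
    config = config,
    config_md5 = cfg_hash,
    input_md5 = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
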
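#' Motion-quality thresholds
#'
#' Image-capture recommendations for a usable view pair: avoid large relative
#' movements (translation above 30 mm or rotation above 30 degrees), minimal
#' movements (displacement below 3 mm), and near pure forward-backward motion
#' along the optical axis, which degenerates two-view triangulation.
#'
#' @param max_translation_mm pair fails `large_translation` when translation is
#'   strictly greater than this.
#' @param max_rotation_deg pair fails `large_rotation` when relative rotation
#'   is strictly greater than this.
#' @param min_translation_mm pair fails `minimal_movement` when translation is
#'   strictly smaller than this.
#' @param forward_angle_deg pair fails `forward_backward` when the angle
#'   between the translation vector and the mean optical axis is strictly
#'   below this.
#' @return A named list of thresholds.
#' @export
motion_thresholds <- function(max_translation_mm = 30,
                              max_rotation_deg = 30,
                              min_translation_mm = 3,
                              forward_angle_deg = 15) {
  stopifnot(max_translation_mm > min_translation_mm,
            max_rotation_deg > 0, min_translation_mm >= 0,
            forward_angle_deg >= 0, forward_angle_deg < 90)
  list(max_translation_mm = max_translation_mm,
       max_rotation_deg = max_rotation_deg,
       min_translation_mm = min_translation_mm,
       forward_angle_deg = forward_angle_deg)
}

#' Check an image pair against the motion recommendations
#'
#' All rules are always evaluated (no short-circuiting) so the report names
#' every violated recommendation. Boundary values pass: the rules use strict
#' inequalities.
#'
#' @param pose_a,pose_b [camera_pose()] objects.
#' @param thresholds a [motion_thresholds()] list.
#' @param rig optional [rig_config()] whose hand-eye transform locates the
#'   camera; identity by default.
#' @return An object of class `pair_quality_report` with the motion scalars,
#'   `passed`, and `failed_rules`.
#' @export
check_pair <- function(pose_a, pose_b, thresholds = motion_thresholds(),
                       rig = NULL) {
  m <- relative_motion(pose_a, pose_b, rig)
  failed <- character(0)
  if (m$translation_mm > thresholds$max_translation_mm)
    failed <- c(failed, "large_translation")
  if (m$rotation_deg > thresholds$max_rotation_deg)
    failed <- c(failed, "large_rotation")
  if (m$translation_mm < thresholds$min_translation_mm)
    failed <- c(failed, "minimal_movement")
  if (m$translation_axis_angle_deg < thresholds$forward_angle_deg)
    failed <- c(failed, "forward_backward")
  structure(list(translation_mm = m$translation_mm,
                 rotation_deg = m$rotation_deg,
                 forward_angle_deg = m$translation_axis_angle_deg,
                 passed = length(failed) == 0,
                 failed_rules = failed),
            class = "pair_quality_report")
}
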
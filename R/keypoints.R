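#' The 27-point body keypoint registry
#'
#' Markerless gait capture streams used by this package carry 27 named body
#' points per frame: 24 estimated directly by the pose tracker (nose, navel and
#' bilateral eyes, ears, shoulders, elbows, wrists, thumbs, middle fingers,
#' hips, knees, ankles and toes) plus 3 derived points (head centre, neck,
#' buttocks). The navel is the reference point; the remaining 26 are the
#' distance targets analysed downstream.
#'
#' Each keypoint carries a region (`trunk` or `limb`) and a level (`upper` or
#' `lower`, relative to the navel). Knees and hips count as trunk; the four
#' taxonomy blocks are upper-trunk (9 points), upper-limb (8), lower-trunk (5)
#' and lower-limb (4).
#'
#' @return A data frame with one row per keypoint, columns `name`, `side`
#'   (`left`/`right`/`midline`), `region`, `level` and `is_target` (FALSE only
#'   for the navel), in the fixed registry order used by all serialization.
#' @examples
#' reg <- keypoint_registry()
#' nrow(reg)                     # 27
#' sum(reg$is_target)            # 26 distance targets
#' table(reg$region[reg$is_target], reg$level[reg$is_target])
#' @export
keypoint_registry <- function() {
  kp <- function(name, side, region, level, target = TRUE) {
    data.frame(name = name, side = side, region = region, level = level,
               is_target = target, stringsAsFactors = FALSE)
  }
  rbind(
    kp("nose",            "midline", "trunk", "upper"),
    kp("eye_r",           "right",   "trunk", "upper"),
    kp("eye_l",           "left",    "trunk", "upper"),
    kp("ear_r",           "right",   "trunk", "upper"),
    kp("ear_l",           "left",    "trunk", "upper"),
    kp("head",            "midline", "trunk", "upper"),
    kp("neck",            "midline", "trunk", "upper"),
    kp("shoulder_r",      "right",   "trunk", "upper"),
    kp("shoulder_l",      "left",    "trunk", "upper"),
    kp("elbow_r",         "right",   "limb",  "upper"),
    kp("elbow_l",         "left",    "limb",  "upper"),
    kp("wrist_r",         "right",   "limb",  "upper"),
    kp("wrist_l",         "left",    "limb",  "upper"),
    kp("thumb_r",         "right",   "limb",  "upper"),
    kp("thumb_l",         "left",    "limb",  "upper"),
    kp("middle_finger_r", "right",   "limb",  "upper"),
    kp("middle_finger_l", "left",    "limb",  "upper"),
    kp("navel",           "midline", "trunk", NA_character_, target = FALSE),
    kp("hip_r",           "right",   "trunk", "lower"),
    kp("hip_l",           "left",    "trunk", "lower"),
    kp("buttocks",        "midline", "trunk", "lower"),
    kp("knee_r",          "right",   "trunk", "lower"),
    kp("knee_l",          "left",    "trunk", "lower"),
    kp("ankle_r",         "right",   "limb",  "lower"),
    kp("ankle_l",         "left",    "limb",  "lower"),
    kp("toe_r",           "right",   "limb",  "lower"),
    kp("toe_l",           "left",    "limb",  "lower")
  )
}

# heel_* are tracker-side names for the ankle points
.keypoint_aliases <- c(heel = "ankle", heel_r = "ankle_r", heel_l = "ankle_l")

#' Resolve a keypoint name, honouring aliases
#'
#' Pose trackers label the ankle points "heels"; `keypoint_lookup()` accepts
#' either name and returns the registry row of the canonical keypoint.
#'
#' @param name A single keypoint name, canonical or alias.
#' @return A one-row data frame (a row of [keypoint_registry()]).
#' @examples
#' keypoint_lookup("heel_l")$name   # "ankle_l"
#' @export
keypoint_lookup <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.keypoint_aliases)) name <- unname(.keypoint_aliases[[name]])
  reg <- keypoint_registry()
  row <- reg[reg$name == name, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("unknown keypoint: '", name, "'", call. = FALSE)
  row
}

#' Names of the 26 navel-distance target keypoints, in registry order
#' @return Character vector of length 26 (all keypoints except the navel).
#' @export
target_keypoints <- function() {
  reg <- keypoint_registry()
  reg$name[reg$is_target]
}

# column names of the trial CSV body: <keypoint>_{x,y,z} in registry order
.coordinate_columns <- function() {
  as.vector(t(outer(keypoint_registry()$name, c("x", "y", "z"), paste, sep = "_")))
}
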
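#' Construct a motion-capture gait trial
#'
#' A `motion_trial` holds one recording: a frames x 27 x 3 array of relative
#' 3D coordinates (the pose tracker's camera-relative, unitless axes) at a
#' stated frame rate, plus subject and group metadata. Coordinates are never
#' interpreted in absolute units; the analysis uses only navel-relative
#' Euclidean distances, which are invariant to whole-body translation.
#'
#' @param coords Numeric array of dimension `c(n_frames, 27, 3)`. The second
#'   dimension must follow (or be named by) the registry order of
#'   [keypoint_registry()]; the third is x, y, z.
#' @param fps Frames per second (Hz); must be positive. Default 30.
#' @param group Cohort label: one of `"iNPH"`, `"PD"`, `"control"`,
#'   `"unknown"`.
#' @param subject_id,trial_id Identifier strings.
#' @return An object of class `motion_trial`.
#' @seealso [read_trial()], [write_trial()], [fluct_fit()]
#' @export
motion_trial <- function(coords, fps = 30, group = "unknown",
                         subject_id = "anon", trial_id = subject_id) {
  reg <- keypoint_registry()
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("'coords' must be a 3-d array (frames x 27 x 3)", call. = FALSE)
  if (dim(coords)[2] != 27L || dim(coords)[3] != 3L)
    stop("'coords' must have dimension n x 27 x 3, got ",
         paste(dim(coords), collapse = " x "), call. = FALSE)
  if (dim(coords)[1] < 1L)
    stop("empty trial: at least one frame is required", call. = FALSE)
  kp_names <- dimnames(coords)[[2]]
  if (is.null(kp_names)) {
    dimnames(coords) <- list(NULL, reg$name, c("x", "y", "z"))
  } else {
    if (!setequal(kp_names, reg$name))
      stop("coords keypoint names do not match the registry", call. = FALSE)
    coords <- coords[, reg$name, , drop = FALSE]
  }
  if (!all(is.finite(coords))) {
    bad <- which(!is.finite(coords), arr.ind = TRUE)
    stop("non-finite coordinate at frame ", bad[1, 1], ", keypoint '",
         reg$name[bad[1, 2]], "'", call. = FALSE)
  }
  fps <- as.numeric(fps)
  if (!is.finite(fps) || fps <= 0) stop("'fps' must be positive", call. = FALSE)
  group <- match.arg(group, c("iNPH", "PD", "control", "unknown"))
  structure(
    list(trial_id = as.character(trial_id), subject_id = as.character(subject_id),
         group = group, fps = fps, coords = coords),
    class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %s  subject=%s  group=%s\n",
              x$trial_id, x$subject_id, x$group))
  cat(sprintf("  %d frames x 27 keypoints @ %g fps (%.1f s)%s\n",
              n_frames(x), x$fps, n_frames(x) / x$fps,
              if (is_eligible(x)) "" else "  [ineligible: < 128 frames]"))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A `motion_trial`.
#' @export
n_frames <- function(trial) dim(trial$coords)[1]

#' Is a trial long enough for the canonical 128-frame analysis?
#' @param trial A `motion_trial`.
#' @param min_frames Minimum frame count; 128 is the canonical window length.
#' @export
is_eligible <- function(trial, min_frames = 128L) n_frames(trial) >= min_frames

# Linear interpolation repair for short dropout gaps. Pose estimators
# occasionally drop frames; gaps of at most `max_gap` consecutive frames per
# coordinate are filled linearly, longer gaps (or edge gaps) are an error.
.repair_gaps <- function(coords, max_gap = 3L) {
  nf <- dim(coords)[1]
  for (k in seq_len(dim(coords)[2])) {
    for (d in 1:3) {
      v <- coords[, k, d]
      if (anyNA(v)) {
        r <- rle(is.na(v))
        if (any(r$lengths[r$values] > max_gap))
          stop("dropout gap longer than ", max_gap, " frames at keypoint '",
               dimnames(coords)[[2]][k], "'; trial rejected", call. = FALSE)
        if (is.na(v[1]) || is.na(v[nf]))
          stop("dropout at trial edge cannot be interpolated", call. = FALSE)
        coords[, k, d] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                        xout = seq_len(nf))$y
      }
    }
  }
  coords
}
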
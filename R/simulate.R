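#' Published group-mean fluctuation indices
#'
#' The packaged reference table of group-mean fluctuation indices reported for
#' a clinical gait study of 117 iNPH, 56 PD and 184 control trials (23, 23 and
#' 92 individuals walking 1-3 laps of a 1 m circle, captured markerlessly at
#' 30 fps): one row per distance-target keypoint with the mean index in each
#' group, the iNPH-vs-PD Tukey p-value and its significance flag at the 5%
#' level. Rows are grouped upper/lower x trunk/limb and ordered within block
#' by ascending absolute control mean, mirroring the published table.
#'
#' These values serve as generation targets for [simulate_cohort()] and as a
#' fixture for cohort-level checks; the underlying per-trial recordings are
#' not public.
#'
#' @return Data frame with columns `keypoint`, `level`, `region`, `control`,
#'   `pd`, `inph`, `p_inph_vs_pd`, `starred` (26 rows).
#' @examples
#' ref <- published_cohort_means()
#' ref[ref$keypoint == "head", ]
#' sum(ref$starred)   # 15 significant iNPH-vs-PD positions
#' @export
published_cohort_means <- function() {
  path <- system.file("extdata", "published_cohort_means.csv",
                      package = "gaitfluct", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Plausible unitless navel-relative skeleton template (y up, x lateral,
# z forward). Magnitudes are arbitrary; only their positivity margin matters:
# simulated distances stay positive as long as noise + cadence < half the
# offset magnitude.
.base_skeleton <- function() {
  off <- list(
    nose            = c( 0.00,  0.50, 0.08),
    eye_r           = c( 0.04,  0.52, 0.07),
    eye_l           = c(-0.04,  0.52, 0.07),
    ear_r           = c( 0.08,  0.50, 0.00),
    ear_l           = c(-0.08,  0.50, 0.00),
    head            = c( 0.00,  0.55, 0.00),
    neck            = c( 0.00,  0.42, 0.00),
    shoulder_r      = c( 0.18,  0.38, 0.00),
    shoulder_l      = c(-0.18,  0.38, 0.00),
    elbow_r         = c( 0.23,  0.12, 0.00),
    elbow_l         = c(-0.23,  0.12, 0.00),
    wrist_r         = c( 0.25, -0.12, 0.02),
    wrist_l         = c(-0.25, -0.12, 0.02),
    thumb_r         = c( 0.26, -0.20, 0.05),
    thumb_l         = c(-0.26, -0.20, 0.05),
    middle_finger_r = c( 0.26, -0.22, 0.03),
    middle_finger_l = c(-0.26, -0.22, 0.03),
    hip_r           = c( 0.10, -0.10, 0.00),
    hip_l           = c(-0.10, -0.10, 0.00),
    buttocks        = c( 0.00, -0.12, -0.06),
    knee_r          = c( 0.11, -0.50, 0.02),
    knee_l          = c(-0.11, -0.50, 0.02),
    ankle_r         = c( 0.12, -0.90, 0.00),
    ankle_l         = c(-0.12, -0.90, 0.00),
    toe_r           = c( 0.12, -0.95, 0.12),
    toe_l           = c(-0.12, -0.95, 0.12))
  off[target_keypoints()]
}

# Resolve the per-keypoint alpha map from scalar / named vector / group name.
.alpha_map <- function(alpha) {
  targets <- target_keypoints()
  if (is.character(alpha)) {
    ref <- published_cohort_means()
    col <- c(control = "control", PD = "pd", iNPH = "inph")[alpha]
    if (is.na(col)) stop("unknown group name '", alpha,
                         "'; use iNPH, PD or control", call. = FALSE)
    out <- stats::setNames(ref[[col]], ref$keypoint)[targets]
  } else if (length(alpha) == 1L) {
    out <- stats::setNames(rep(as.numeric(alpha), length(targets)), targets)
  } else {
    if (is.null(names(alpha)) || !setequal(names(alpha), targets))
      stop("per-keypoint 'alpha' must be named by the 26 target keypoints",
           call. = FALSE)
    out <- as.numeric(alpha[targets])
    names(out) <- targets
  }
  if (any(!is.finite(out))) stop("non-finite alpha target", call. = FALSE)
  out
}

#' Simulate one gait trial with prescribed spectral exponents
#'
#' Builds a synthetic circular-walking recording whose navel-relative distance
#' series have known log-log PSD slopes. The navel traces one lap of a circle
#' of diameter 1; every target keypoint `p` sits at
#' `navel + u_p * (d0_p + g_p(t) + s_p(t))`, where `u_p` and `d0_p` are the
#' direction and magnitude of a fixed skeleton offset, `g_p` an optional
#' cadence sinusoid and `s_p` a power-law noise series with the keypoint's
#' target exponent. The distance from the navel is therefore *exactly*
#' `d0_p + g_p + s_p`: in deterministic-amplitude mode with `cadence_amp = 0`
#' the downstream fluctuation index recovers each target exponent to machine
#' precision, which anchors the package's correctness tests.
#'
#' @param alpha Target exponent(s): a single number for all keypoints, a named
#'   vector over the 26 target keypoints, or a group name (`"iNPH"`, `"PD"`,
#'   `"control"`) selecting the corresponding column of
#'   [published_cohort_means()].
#' @param n_frames Frames to simulate (default 128, the canonical window).
#' @param fps Frame rate in Hz.
#' @param mode Noise synthesis mode, see [powerlaw_series()].
#' @param noise_rms Root-mean-square amplitude of each keypoint's noise series
#'   (unitless, relative to skeleton offsets of order 0.1-1).
#' @param cadence_hz Step frequency of the optional gait sinusoid (Hz).
#' @param cadence_amp Amplitude of the cadence sinusoid relative to
#'   `noise_rms`; 0 (the default) for estimator-validation runs, since a
#'   spectral line biases the slope fit.
#' @param group,subject_id,trial_id Trial metadata.
#' @param seed Optional integer for reproducibility.
#' @return A [motion_trial()].
#' @examples
#' tr <- simulate_trial(alpha = -2.15, seed = 7)
#' coef(fluct_fit(tr))[1:3]    # all -2.15
#' @export
simulate_trial <- function(alpha = -2, n_frames = 128L, fps = 30,
                           mode = c("stochastic", "deterministic_amplitude"),
                           noise_rms = 0.01, cadence_hz = 1, cadence_amp = 0,
                           group = "unknown", subject_id = "sim",
                           trial_id = subject_id, seed = NULL) {
  mode <- match.arg(mode)
  if (cadence_amp < 0) stop("'cadence_amp' must be >= 0", call. = FALSE)
  if (noise_rms <= 0) stop("'noise_rms' must be > 0", call. = FALSE)
  amap <- .alpha_map(alpha)
  skel <- .base_skeleton()
  .with_seed(seed, {
    t_idx <- seq_len(n_frames) - 1L
    theta <- 2 * pi * t_idx / n_frames          # one lap per trial
    navel <- cbind(0.5 * cos(theta), 0, 0.5 * sin(theta))
    coords <- array(NA_real_, dim = c(n_frames, 27L, 3L),
                    dimnames = list(NULL, keypoint_registry()$name,
                                    c("x", "y", "z")))
    coords[, "navel", ] <- navel
    for (k in names(amap)) {
      d0 <- sqrt(sum(skel[[k]]^2))
      u <- skel[[k]] / d0
      s <- powerlaw_series(n_frames, amap[[k]], fs = fps, mode = mode)
      s <- s * noise_rms / sqrt(mean(s^2))
      g <- if (cadence_amp > 0)
        cadence_amp * noise_rms *
          sin(2 * pi * cadence_hz * t_idx / fps + stats::runif(1, 0, 2 * pi))
      else 0
      wobble <- g + s
      if (max(abs(wobble)) >= d0 / 2)
        stop("noise too large for skeleton offset of keypoint '", k,
             "' (", signif(d0, 3), "); reduce noise_rms or cadence_amp",
             call. = FALSE)
      coords[, k, ] <- navel + outer(d0 + wobble, u)
    }
    motion_trial(coords, fps = fps, group = group,
                 subject_id = subject_id, trial_id = trial_id)
  })
}

#' Simulate a three-group gait cohort
#'
#' Generates labelled trials for the iNPH, PD and control groups. Each trial's
#' per-keypoint exponents are the group's target map plus one shared Gaussian
#' between-trial offset drawn with standard deviation `alpha_sd` (a trial is
#' globally better or worse, mirroring day-to-day symptom fluctuation).
#' Defaults reproduce the published study conditions: 117/56/184 trials over
#' 23/23/92 subjects, group target maps from [published_cohort_means()],
#' 128 frames at 30 fps.
#'
#' @param n_trials Named integer vector of trial counts per group.
#' @param alpha Named list mapping each group to its target exponent spec
#'   (anything [simulate_trial()] accepts); default: the published group
#'   columns.
#' @param alpha_sd Between-trial exponent standard deviation (>= 0);
#'   default 0.15 (the published table reports no dispersions; this is a
#'   simulation parameter, not an estimate of them).
#' @param n_subjects Named integer vector; trials are assigned round-robin to
#'   subjects within group.
#' @param n_frames,fps,mode,noise_rms,cadence_hz,cadence_amp Passed to
#'   [simulate_trial()].
#' @param seed Optional integer; the whole cohort is a pure function of the
#'   arguments and the seed.
#' @return List of [motion_trial()] objects (length `sum(n_trials)`).
#' @examples
#' trials <- simulate_cohort(n_trials = c(iNPH = 3, PD = 3, control = 3),
#'                           alpha_sd = 0, mode = "deterministic_amplitude",
#'                           seed = 1)
#' length(trials)
#' @export
simulate_cohort <- function(n_trials = c(iNPH = 117L, PD = 56L, control = 184L),
                            alpha = list(iNPH = "iNPH", PD = "PD",
                                         control = "control"),
                            alpha_sd = 0.15,
                            n_subjects = c(iNPH = 23L, PD = 23L, control = 92L),
                            n_frames = 128L, fps = 30,
                            mode = c("stochastic", "deterministic_amplitude"),
                            noise_rms = 0.01, cadence_hz = 1, cadence_amp = 0,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (alpha_sd < 0) stop("'alpha_sd' must be >= 0", call. = FALSE)
  groups <- names(n_trials)
  if (is.null(groups) || !all(groups %in% c("iNPH", "PD", "control")))
    stop("'n_trials' must be named by groups iNPH, PD, control", call. = FALSE)
  if (any(n_trials < 2L))
    stop("at least 2 trials per group are required for group comparison",
         call. = FALSE)
  .with_seed(seed, {
    out <- vector("list", sum(n_trials))
    i <- 0L
    for (g in groups) {
      gmap <- .alpha_map(alpha[[g]])
      nsub <- max(1L, as.integer(n_subjects[[g]] %||% n_trials[[g]]))
      for (j in seq_len(n_trials[[g]])) {
        shift <- if (alpha_sd > 0) stats::rnorm(1, 0, alpha_sd) else 0
        sid <- sprintf("%s_s%02d", g, ((j - 1L) %% nsub) + 1L)
        i <- i + 1L
        out[[i]] <- simulate_trial(
          alpha = gmap + shift, n_frames = n_frames, fps = fps, mode = mode,
          noise_rms = noise_rms, cadence_hz = cadence_hz,
          cadence_amp = cadence_amp, group = g, subject_id = sid,
          trial_id = sprintf("%s_t%03d", g, j))
      }
    }
    out
  })
}
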
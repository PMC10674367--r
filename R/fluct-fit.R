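#' Fit fluctuation indices to a gait trial
#'
#' The central estimator. For each of the 26 target keypoints the per-frame
#' Euclidean distance to the navel is computed, one contiguous analysis window
#' is extracted ([extract_window()]), its one-sided raw periodogram taken
#' ([psd_periodogram()]) and the slope of log10 power on log10 frequency
#' fitted by ordinary least squares ([fit_loglog()]). That slope is the
#' keypoint's *fluctuation index*: near 0 the distance series varies like
#' white noise (uncorrelated, "too random"), near -1 like 1/f pink noise (the
#' long-range-correlated structure of healthy movement variability), near -2
#' like Brownian noise.
#'
#' @param trial A [motion_trial()] with at least `window_length` frames.
#' @param window Window selection strategy, see [extract_window()].
#' @param window_length Window length in frames. 128 is the canonical length
#'   (about 4 s at 30 fps); other even lengths >= 8 are accepted but flagged
#'   as non-canonical in the fitted object.
#' @param edge_trim Frames ignored at each end by the stable-window search.
#' @param f_min,f_max Optional frequency band (Hz) for the log-log fit;
#'   default all positive non-Nyquist bins (63 bins at n = 128).
#' @param start Start frame when `window = "fixed_start"`.
#' @return An object of class `fluct_fit`: per-keypoint slopes with fit
#'   diagnostics and the underlying periodograms. Methods: [coef()] (named
#'   slope vector), `print`, `summary` (data-frame of all diagnostics),
#'   `plot` (log-log periodogram with the fitted line), `residuals`
#'   (log10-domain fit residuals per keypoint).
#' @examples
#' tr <- simulate_trial(alpha = "control", mode = "deterministic_amplitude",
#'                      seed = 42)
#' fit <- fluct_fit(tr)
#' round(coef(fit)[c("head", "ankle_r")], 2)
#' @export
fluct_fit <- function(trial, window = c("stable", "centered", "fixed_start"),
                      window_length = 128L, edge_trim = 30L,
                      f_min = NULL, f_max = NULL, start = 1L) {
  stopifnot(inherits(trial, "motion_trial"))
  window <- match.arg(window)
  if (!is_eligible(trial, window_length))
    stop("ineligible trial '", trial$trial_id, "': ", n_frames(trial),
         " frames, analysis needs at least ", window_length, call. = FALSE)
  dist <- navel_distances(trial)
  targets <- colnames(dist)
  fits <- vector("list", length(targets))
  psds <- vector("list", length(targets))
  names(fits) <- names(psds) <- targets
  for (k in targets) {
    w <- extract_window(dist[, k], strategy = window, length = window_length,
                        edge_trim = edge_trim, start = start)
    psd <- tryCatch(psd_periodogram(w, fs = trial$fps),
                    error = function(e)
                      stop("keypoint '", k, "': ", conditionMessage(e),
                           call. = FALSE))
    fits[[k]] <- tryCatch(fit_loglog(psd, f_min = f_min, f_max = f_max),
                          error = function(e)
                            stop("keypoint '", k, "': ", conditionMessage(e),
                                 call. = FALSE))
    psds[[k]] <- psd
  }
  indices <- data.frame(
    keypoint = targets,
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    log_k = vapply(fits, `[[`, numeric(1), "log_k"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_bins = vapply(fits, `[[`, integer(1), "n_bins"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(indices = indices, psd = psds,
         trial_id = trial$trial_id, subject_id = trial$subject_id,
         group = trial$group, fps = trial$fps,
         window = window, window_length = as.integer(window_length),
         canonical = window_length == 128L,
         band = c(f_min = f_min %||% NA_real_, f_max = f_max %||% NA_real_)),
    class = "fluct_fit")
}

#' @export
coef.fluct_fit <- function(object, ...) {
  stats::setNames(object$indices$alpha, object$indices$keypoint)
}

#' @export
print.fluct_fit <- function(x, digits = 3, ...) {
  a <- coef(x)
  cat(sprintf("<fluct_fit> trial=%s  group=%s  window=%s(%d)%s\n",
              x$trial_id, x$group, x$window, x$window_length,
              if (x$canonical) "" else " [non-canonical length]"))
  cat(sprintf("  fluctuation index: mean %.3f, range [%.3f, %.3f] over %d keypoints\n",
              mean(a), min(a), max(a), length(a)))
  invisible(x)
}

#' @export
summary.fluct_fit <- function(object, ...) {
  out <- object$indices
  out$trial_id <- object$trial_id
  out$subject_id <- object$subject_id
  out$group <- object$group
  out[, c("trial_id", "subject_id", "group", "keypoint",
          "alpha", "log_k", "r_squared", "n_bins")]
}

#' @export
residuals.fluct_fit <- function(object, keypoint = NULL, ...) {
  kps <- if (is.null(keypoint)) object$indices$keypoint else keypoint
  out <- lapply(kps, function(k) {
    psd <- object$psd[[k]]
    row <- object$indices[object$indices$keypoint == k, ]
    pos <- psd$power > 0
    log10(psd$power[pos]) - (row$log_k + row$alpha * log10(psd$freq[pos]))
  })
  names(out) <- kps
  if (length(out) == 1L) out[[1]] else out
}

#' Plot the log-log periodogram and fitted slope for one keypoint
#'
#' @param x A `fluct_fit`.
#' @param keypoint Keypoint to display (default `"head"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fluct_fit <- function(x, keypoint = "head", ...) {
  psd <- x$psd[[keypoint]]
  if (is.null(psd)) stop("no fitted keypoint '", keypoint, "'", call. = FALSE)
  row <- x$indices[x$indices$keypoint == keypoint, ]
  graphics::plot(log10(psd$freq), log10(psd$power),
                 xlab = "log10 frequency (Hz)", ylab = "log10 PSD",
                 main = sprintf("%s: alpha = %.2f (R2 = %.2f)",
                                keypoint, row$alpha, row$r_squared), ...)
  graphics::abline(a = row$log_k, b = row$alpha, col = 2, lwd = 2)
  invisible(x)
}

#' Per-keypoint fluctuation indices of one trial as a data frame
#'
#' Convenience wrapper around [fluct_fit()] returning only the index table
#' (trial metadata plus alpha, intercept, R-squared and bin count per
#' keypoint).
#'
#' @inheritParams fluct_fit
#' @param ... Passed to [fluct_fit()].
#' @return Data frame with 26 rows.
#' @export
fluctuation_indices <- function(trial, ...) summary(fluct_fit(trial, ...))
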
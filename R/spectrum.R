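#' Navel-relative distance series for all target keypoints
#'
#' Reduces a trial to 26 per-frame Euclidean distances from the navel, one per
#' target keypoint. Distances are invariant to whole-body translation, so the
#' pose tracker's arbitrary camera-relative origin drops out.
#'
#' @param trial A [motion_trial()].
#' @return A numeric matrix, frames x 26, columns named by target keypoint.
#' @examples
#' tr <- simulate_trial(alpha = -2, seed = 1)
#' d <- navel_distances(tr)
#' dim(d)   # 128 x 26
#' @export
navel_distances <- function(trial) {
  stopifnot(inherits(trial, "motion_trial"))
  navel <- trial$coords[, "navel", , drop = FALSE]
  targets <- target_keypoints()
  out <- sapply(targets, function(k) {
    delta <- trial$coords[, k, ] - navel[, 1, ]
    sqrt(rowSums(matrix(delta, ncol = 3L)^2))
  })
  matrix(out, ncol = length(targets), dimnames = list(NULL, targets))
}

#' Extract the analysis window from a distance series
#'
#' The canonical analysis uses one contiguous 128-frame (~4 s at 30 fps) slice
#' per trial, taken where the walk is as stable as possible — away from the
#' start-up and stopping transients. Strategies:
#' \describe{
#'   \item{`stable`}{after discarding `edge_trim` frames at both ends, scan all
#'     admissible start positions and pick the window minimizing the variance
#'     of the first differences of the series (ties broken by the earliest
#'     start). Falls back to `centered` when the series is too short to trim.}
#'   \item{`centered`}{the middle slice.}
#'   \item{`fixed_start`}{frames `[start, start + length)`.}
#' }
#'
#' @param x Numeric distance series (one keypoint).
#' @param strategy `"stable"`, `"centered"` or `"fixed_start"`.
#' @param length Window length in frames; default 128, the canonical choice
#'   (a power of two spanning about 4 s at 30 fps).
#' @param edge_trim Frames discarded at each end before the stable search.
#' @param start 1-based start frame for `fixed_start`.
#' @return Numeric vector of `length` frames.
#' @export
extract_window <- function(x, strategy = c("stable", "centered", "fixed_start"),
                           length = 128L, edge_trim = 30L, start = 1L) {
  strategy <- match.arg(strategy)
  n <- base::length(x)
  if (n < length)
    stop("ineligible trial: series has ", n, " frames, needs at least ",
         length, call. = FALSE)
  if (strategy == "fixed_start") {
    if (start < 1L || start + length - 1L > n)
      stop("fixed_start window [", start, ", ", start + length - 1L,
           "] outside series", call. = FALSE)
    return(x[start:(start + length - 1L)])
  }
  if (strategy == "stable" && n >= length + 2L * edge_trim) {
    starts <- (edge_trim + 1L):(n - edge_trim - length + 1L)
    dx <- diff(x)
    # variance of first differences within each candidate window
    score <- vapply(starts, function(s)
      stats::var(dx[s:(s + length - 2L)]), numeric(1))
    best <- starts[which.min(score)]       # which.min takes the earliest tie
    return(x[best:(best + length - 1L)])
  }
  # centered (and the stable fallback for short series)
  s <- (n - length) %/% 2L + 1L
  x[s:(s + length - 1L)]
}

#' One-sided raw periodogram of a windowed series
#'
#' The window mean is subtracted (no further detrending, no taper), the
#' discrete Fourier transform taken, and the one-sided power spectral density
#' \deqn{P_i = \frac{2}{n f_s} |X_i|^2} reported at the Fourier frequencies
#' \eqn{f_i = i f_s / n}, for \eqn{i = 1, \dots, n/2 - 1}. DC and the Nyquist
#' bin are excluded: DC is zero after mean removal and both are outside the
#' log-log fitting range. For n = 128 at 30 fps this yields 63 ordinates from
#' 0.234 Hz to 14.766 Hz.
#'
#' @param x Numeric series of even length >= 8.
#' @param fs Sampling rate (Hz).
#' @return An object of class `gait_psd`: list with `freq` (Hz, ascending),
#'   `power` (unitless^2/Hz), `n` and `fs`.
#' @export
psd_periodogram <- function(x, fs = 30) {
  n <- length(x)
  if (n %% 2L != 0L || n < 8L)
    stop("window length must be even and at least 8", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in window", call. = FALSE)
  x <- x - mean(x)
  if (all(x == 0))
    stop("degenerate spectrum: window is constant, slope undefined",
         call. = FALSE)
  X <- stats::fft(x)
  i <- 2:(n %/% 2L)                        # bins 1 .. n/2-1
  structure(list(freq = (i - 1L) * fs / n,
                 power = (2 / (n * fs)) * Mod(X[i])^2,
                 n = n, fs = fs),
            class = "gait_psd")
}

#' @export
print.gait_psd <- function(x, ...) {
  cat(sprintf("<gait_psd> %d bins, %.3f-%.3f Hz (n=%d @ %g Hz)\n",
              length(x$freq), min(x$freq), max(x$freq), x$n, x$fs))
  invisible(x)
}

#' Fit the log-log spectral slope (the fluctuation index)
#'
#' Ordinary least squares of log10 power on log10 frequency over the
#' periodogram bins, optionally restricted to a frequency band. The fitted
#' slope \eqn{\alpha} of \eqn{\log P(f) = \alpha \log f + \log k} is the
#' fluctuation index: around 0 for white (uncorrelated) noise, around -1 for
#' 1/f (pink) noise, around -2 for Brownian noise. The slope is invariant to
#' the log base and to rescaling the series; the intercept `log_k` is reported
#' in base 10. Bins with exactly zero power (possible only for degenerate or
#' synthetic input) are dropped from the fit and counted.
#'
#' @param psd A `gait_psd` from [psd_periodogram()].
#' @param f_min,f_max Optional band limits in Hz (inclusive); default all bins.
#' @return List with `alpha`, `log_k`, `r_squared`, `n_bins` (bins used) and
#'   `n_dropped` (zero-power bins excluded).
#' @examples
#' p <- psd_periodogram(powerlaw_series(128, -2, seed = 1), fs = 30)
#' fit_loglog(p)$alpha      # exactly -2
#' @export
fit_loglog <- function(psd, f_min = NULL, f_max = NULL) {
  stopifnot(inherits(psd, "gait_psd"))
  keep <- rep(TRUE, length(psd$freq))
  if (!is.null(f_min)) keep <- keep & psd$freq >= f_min
  if (!is.null(f_max)) keep <- keep & psd$freq <= f_max
  f <- psd$freq[keep]; p <- psd$power[keep]
  pos <- p > 0
  n_dropped <- sum(!pos)
  f <- f[pos]; p <- p[pos]
  if (length(f) < 3L)
    stop("degenerate fit: fewer than 3 positive power bins", call. = FALSE)
  lx <- log10(f); ly <- log10(p)
  sxx <- sum((lx - mean(lx))^2)
  alpha <- sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
  log_k <- mean(ly) - alpha * mean(lx)
  ss_res <- sum((ly - (log_k + alpha * lx))^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(alpha = alpha, log_k = log_k, r_squared = r2,
       n_bins = length(f), n_dropped = n_dropped)
}
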
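#' Synthesize a power-law (colored) noise series
#'
#' Generates a real series of even length `n` whose one-sided power spectral
#' density follows \eqn{P(f) = scale \cdot f^{\alpha}}. Synthesis is spectral:
#' the positive-frequency Fourier coefficients are constructed directly and the
#' series recovered by inverse FFT, so the spectral law is imposed exactly
#' rather than approximately.
#'
#' Two modes are offered:
#' \describe{
#'   \item{`deterministic_amplitude`}{amplitudes fixed at
#'     \eqn{|X_i|^2 = n f_s P(f_i)/2}, phases uniform random. The raw
#'     periodogram of the output equals `scale * f^alpha` *exactly* at every
#'     positive non-Nyquist Fourier frequency, for any seed — this makes
#'     downstream slope estimation an exact-recovery test.}
#'   \item{`stochastic`}{coefficients are independent complex Gaussians with
#'     variance proportional to \eqn{f^{\alpha}}; each periodogram ordinate is
#'     then an exponential variate with mean `scale * f^alpha`, the usual
#'     statistical behaviour of a periodogram of Gaussian colored noise.}
#' }
#' The DC coefficient is zero (the series has exactly zero mean) and the
#' Nyquist coefficient is zero.
#'
#' @param n Series length; even, at least 8.
#' @param alpha Target log-log PSD slope (dimensionless; 0 = white noise,
#'   about -1 = pink/1/f noise, about -2 = Brownian noise).
#' @param fs Sampling rate in Hz (default 30, the pose tracker's frame rate).
#' @param scale PSD amplitude multiplier (> 0); moves the log-log intercept,
#'   never the slope.
#' @param mode `"deterministic_amplitude"` or `"stochastic"`.
#' @param seed Optional integer; when given, output is a pure function of the
#'   arguments (the caller's RNG state is left untouched).
#' @return Numeric vector of length `n` with zero mean.
#' @examples
#' x <- powerlaw_series(128, alpha = -2, seed = 1)
#' fit_loglog(psd_periodogram(x, fs = 30))$alpha   # -2 to machine precision
#' @export
powerlaw_series <- function(n, alpha, fs = 30, scale = 1,
                            mode = c("deterministic_amplitude", "stochastic"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (n %% 2L != 0L || n < 8L)
    stop("'n' must be even and at least 8", call. = FALSE)
  if (!is.finite(alpha) || !is.finite(scale) || scale <= 0)
    stop("'alpha' must be finite and 'scale' finite and positive", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  .with_seed(seed, {
    half <- n %/% 2L
    f <- (1:(half - 1L)) * fs / n
    target <- scale * f^alpha                 # one-sided PSD at each bin
    if (mode == "deterministic_amplitude") {
      amp <- sqrt(target * n * fs / 2)
      phase <- stats::runif(half - 1L, 0, 2 * pi)
      X <- amp * exp(1i * phase)
    } else {
      sd_part <- sqrt(target * n * fs / 4)
      X <- complex(real = stats::rnorm(half - 1L, sd = sd_part),
                   imaginary = stats::rnorm(half - 1L, sd = sd_part))
    }
    full <- c(0 + 0i, X, 0 + 0i, Conj(rev(X)))
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed. With seed = NULL, uses (and advances) the global RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
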
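test_that("navel distances are Euclidean and translation-invariant", {
  tr <- make_static_trial(offset = c(3, 4, 0))
  d <- navel_distances(tr)
  expect_equal(dim(d), c(128L, 26L))
  expect_true(all(abs(d - 5) < 1e-12))          # 3-4-5 triangle
  expect_false("navel" %in% colnames(d))

  # translate every keypoint (navel included) by a random per-frame vector
  tr2 <- tr
  set.seed(5)
  shift <- matrix(rnorm(128 * 3), 128, 3)
  for (k in dimnames(tr2$coords)[[2]])
    tr2$coords[, k, ] <- tr2$coords[, k, ] + shift
  expect_equal(navel_distances(tr2), d, tolerance = 1e-12)
})

test_that("window extraction follows strategy and tie-break rules", {
  # linear series: all windows tie on var(diff) -> earliest admissible start
  x <- as.numeric(1:200)
  expect_equal(extract_window(x, "stable"), x[31:158])
  # exact-length series: every strategy returns the full series
  y <- rnorm(128)
  for (s in c("stable", "centered", "fixed_start"))
    expect_identical(extract_window(y, s), y)
  # centered takes the middle slice
  expect_equal(extract_window(x, "centered"), x[37:164])
  # fixed_start honours its start
  expect_equal(extract_window(x, "fixed_start", start = 10), x[10:137])
  expect_error(extract_window(x, "fixed_start", start = 100), "outside")
  # too short for trimming: stable falls back to centered
  z <- rnorm(150)
  expect_identical(extract_window(z, "stable"), extract_window(z, "centered"))
  expect_error(extract_window(rnorm(100)), "ineligible")
})

test_that("stable window finds the quiet segment (brute-force oracle)", {
  set.seed(12)
  x <- c(rnorm(120, sd = 1), rnorm(160, sd = 0.01), rnorm(120, sd = 1))
  w <- extract_window(x, "stable")
  s_oracle <- oracle_stable_start(x)
  expect_identical(w, x[s_oracle:(s_oracle + 127L)])
  expect_true(s_oracle >= 121 && s_oracle + 127 <= 280)
})

test_that("periodogram matches DFT theory bin by bin", {
  n <- 128; fs <- 30; a <- 0.7
  t <- 0:(n - 1)
  x <- a * cos(2 * pi * 4 * t / n)              # bin-centered cosine, bin 4
  p <- psd_periodogram(x, fs = fs)
  expect_length(p$freq, 63L)
  expect_equal(p$freq[1], fs / n)
  expect_equal(p$freq[63], 63 * fs / n)
  expect_lt(abs(p$power[4] - (2 / (n * fs)) * (n * a / 2)^2), 1e-10)
  expect_lt(max(p$power[-4]), 1e-20)

  # Parseval: integrated PSD ~ window variance for broadband input
  set.seed(30)
  w <- rnorm(n)
  pw <- psd_periodogram(w, fs = fs)
  v <- sum((w - mean(w))^2) / n
  expect_lt(abs(sum(pw$power * fs / n) - v) / v, 0.05)

  expect_error(psd_periodogram(rep(1, 128)), "degenerate spectrum")
  expect_error(psd_periodogram(rnorm(127)), "even")
})

test_that("log-log fit recovers exact power laws and is scale-invariant", {
  f <- (1:63) * 30 / 128
  mk <- function(power) structure(list(freq = f, power = power,
                                       n = 128L, fs = 30), class = "gait_psd")
  fit <- fit_loglog(mk(f^-2))
  expect_equal(fit$alpha, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_bins, 63L)

  fit_c <- fit_loglog(mk(7.3 * f^-2))
  expect_equal(fit_c$alpha, -2, tolerance = 1e-12)
  expect_equal(fit_c$log_k - fit$log_k, log10(7.3), tolerance = 1e-12)

  # zero-power bins are dropped and counted; too few bins is an error
  pz <- f^-1; pz[c(2, 5)] <- 0
  fz <- fit_loglog(mk(pz))
  expect_equal(fz$n_dropped, 2L)
  expect_equal(fz$n_bins, 61L)
  few <- c(1, 2, 0, rep(0, 60))
  expect_error(fit_loglog(mk(few)), "fewer than 3")

  # band restriction
  fb <- fit_loglog(mk(f^-2), f_min = 1, f_max = 10)
  expect_equal(fb$alpha, -2, tolerance = 1e-12)
  expect_lt(fb$n_bins, 63L)
})

test_that("trial-level fit composes the stages exactly", {
  ref <- published_cohort_means()
  amap <- stats::setNames(ref$inph, ref$keypoint)
  tr <- simulate_trial(alpha = amap, mode = "deterministic_amplitude",
                       seed = 13, group = "iNPH")
  fit <- fluct_fit(tr)
  expect_lt(max(abs(coef(fit)[ref$keypoint] - ref$inph)), 1e-6)
  expect_equal(nrow(summary(fit)), 26L)
  expect_true(all(summary(fit)$n_bins == 63L))
  expect_true(all(summary(fit)$r_squared > 0.99))
})

test_that("slope is invariant to amplitude scaling and constant offsets", {
  tr <- simulate_trial(alpha = -1.7, mode = "deterministic_amplitude",
                       seed = 19)
  a0 <- coef(fluct_fit(tr))
  # rescaling all coordinates rescales all distances
  tr_scaled <- tr
  tr_scaled$coords <- tr$coords * 4.2
  fit_s <- fluct_fit(tr_scaled)
  expect_lt(max(abs(coef(fit_s) - a0)), 1e-9)
  expect_equal(fit_s$indices$log_k - fluct_fit(tr)$indices$log_k,
               rep(2 * log10(4.2), 26L), tolerance = 1e-9)
  # constant offsets are removed by mean subtraction
  d <- navel_distances(tr)[, "head"]
  expect_lt(abs(pipeline_slope(d + 100) - pipeline_slope(d)), 1e-9)
})

test_that("stable and centered windows agree on stationary input on average", {
  diffs <- vapply(1:10, function(s) {
    x <- powerlaw_series(400, -2, mode = "stochastic", seed = s)
    pipeline_slope(extract_window(x, "stable")) -
      pipeline_slope(extract_window(x, "centered"))
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.19)
})

test_that("fit diagnostics and accessors are consistent", {
  tr <- simulate_trial(alpha = -2, mode = "stochastic", seed = 3)
  fit <- fluct_fit(tr)
  expect_named(coef(fit), target_keypoints(), ignore.order = TRUE)
  r <- residuals(fit, "head")
  row <- fit$indices[fit$indices$keypoint == "head", ]
  expect_length(r, row$n_bins)
  expect_lt(abs(mean(r)), 1e-10)                # OLS residuals are centred
  expect_identical(fluctuation_indices(tr), summary(fit))
})
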
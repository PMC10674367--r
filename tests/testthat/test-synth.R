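test_that("deterministic-amplitude synthesis imposes the exact spectral law", {
  # flat spectrum at alpha = 0
  x <- powerlaw_series(128, 0, fs = 30, mode = "deterministic_amplitude",
                       seed = 1)
  expect_lt(abs(pipeline_slope(x)), 1e-9)
  expect_lt(abs(mean(x)), 1e-12)

  # exact slope recovery across the whole grid, estimator monotone in target
  grid <- seq(0, -3, by = -0.25)
  est <- vapply(grid, function(a)
    pipeline_slope(powerlaw_series(128, a, mode = "deterministic_amplitude",
                                   seed = 11)), numeric(1))
  expect_lt(max(abs(est - grid)), 1e-9)
  expect_true(all(diff(est) < 0))

  # phase invariance: any seed gives the same periodogram
  for (s in c(5, 6, 7)) {
    y <- powerlaw_series(128, -2, mode = "deterministic_amplitude", seed = s)
    expect_lt(abs(pipeline_slope(y) + 2), 1e-9)
  }
})

test_that("stochastic synthesis is unbiased for the slope", {
  est <- vapply(1:300, function(s)
    pipeline_slope(powerlaw_series(128, -1, mode = "stochastic", seed = s)),
    numeric(1))
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) + 1), 3 * sem + 1e-12)
  expect_lt(abs(mean(est) + 1), 0.05)
})

test_that("synthesis is deterministic given a seed and validates input", {
  expect_identical(powerlaw_series(128, -1, seed = 4),
                   powerlaw_series(128, -1, seed = 4))
  expect_error(powerlaw_series(127, -1), "even")
  expect_error(powerlaw_series(4, -1), "even|at least 8")
  expect_error(powerlaw_series(128, NA_real_), "finite")
  expect_error(powerlaw_series(128, -1, scale = -1), "positive")
  # seeded call leaves the caller's RNG stream untouched
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(powerlaw_series(128, -1, seed = 123))
  expect_identical(rnorm(1), before)
})

test_that("simulated trials carry the prescribed exponents exactly", {
  tr <- simulate_trial(alpha = -2.15, mode = "deterministic_amplitude",
                       seed = 21)
  a <- coef(fluct_fit(tr))
  expect_length(a, 26L)
  expect_lt(max(abs(a + 2.15)), 1e-6)

  # same seed, same trial; distances stay positive
  tr2 <- simulate_trial(alpha = -2.15, mode = "deterministic_amplitude",
                        seed = 21)
  expect_identical(tr$coords, tr2$coords)
  expect_true(all(navel_distances(tr) > 0))
})

test_that("trial generation rejects impossible specs", {
  short <- simulate_trial(n_frames = 100L, seed = 1)
  expect_error(fluct_fit(short), "ineligible")
  expect_error(simulate_trial(noise_rms = 1, seed = 1), "reduce noise_rms")
  expect_error(simulate_trial(alpha = "NPH"), "unknown group")
})

test_that("cadence component keeps distances positive and the trial valid", {
  tr <- simulate_trial(alpha = -2, cadence_amp = 0.1, cadence_hz = 1,
                       mode = "stochastic", seed = 8)
  expect_true(all(navel_distances(tr) > 0))
  expect_s3_class(fluct_fit(tr), "fluct_fit")
})

test_that("cohort generation is labelled, sized and reproducible", {
  n <- c(iNPH = 3L, PD = 2L, control = 4L)
  trials <- simulate_cohort(n_trials = n, alpha_sd = 0.1, seed = 31)
  expect_length(trials, 9L)
  expect_equal(table(vapply(trials, `[[`, character(1), "group")),
               table(rep(names(n), n)))
  again <- simulate_cohort(n_trials = n, alpha_sd = 0.1, seed = 31)
  expect_identical(lapply(trials, `[[`, "coords"),
                   lapply(again, `[[`, "coords"))
  expect_error(simulate_cohort(n_trials = c(iNPH = 0L, PD = 2L, control = 2L)),
               "at least 2 trials")
  expect_error(simulate_cohort(n_trials = c(a = 3L, b = 3L)), "named by groups")
})

test_that("identical group alpha maps yield no spurious group differences", {
  trials <- simulate_cohort(n_trials = c(iNPH = 4L, PD = 4L, control = 4L),
                            alpha = list(iNPH = -2, PD = -2, control = -2),
                            alpha_sd = 0.1, mode = "deterministic_amplitude",
                            seed = 17)
  co <- fluct_cohort(trials)
  expect_true(all(co$table$anova_p > 0.05))
  expect_equal(sum(co$table$star), 0L)
})
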
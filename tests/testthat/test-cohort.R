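test_that("one-way ANOVA matches theory and handles degenerate input", {
  # identical groups: no between-group variation
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g), list(F = 0, p = 1, df1 = 2L, df2 = 6L))
  # zero within-group variance, unequal means
  z <- one_way_anova(list(c(0, 0), c(0, 0), c(10, 10)))
  expect_equal(z$F, Inf)
  expect_equal(z$p, 0)
  # all observations identical
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2)))$p, 1)
  # classical case, against the hand computation and the stats::aov oracle:
  # between-SS 4 (df 2), within-SS 1.5 (df 3) -> F = 4
  h <- one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(h$F, 4)
  oracle <- anova(lm(y ~ g, data.frame(y = c(1, 2, 2, 3, 3, 4),
                                       g = factor(rep(1:3, each = 2)))))
  expect_equal(h$F, oracle$`F value`[1])
  expect_equal(h$p, oracle$`Pr(>F)`[1])
  expect_error(one_way_anova(list(1:3)), "at least 2 groups")
  expect_error(one_way_anova(list(1, 1:3)), "at least 2 observations")
})

test_that("ANOVA p is monotone decreasing in F at fixed df", {
  ps <- pf(c(0.5, 1, 2, 4, 8), 2, 20, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  # and F is never negative on random data
  set.seed(41)
  for (i in 1:20) {
    g <- lapply(1:3, function(j) rnorm(sample(3:8, 1)))
    expect_gte(one_way_anova(g)$F, 0)
  }
})

test_that("Tukey HSD matches the stats::TukeyHSD oracle", {
  set.seed(77)
  for (i in 1:25) {
    sizes <- sample(3:9, 3, replace = TRUE)
    g <- lapply(sizes, function(n) rnorm(n, mean = runif(1, -1, 1)))
    names(g) <- c("a", "b", "c")
    mine <- tukey_hsd(g)
    df <- data.frame(y = unlist(g), f = factor(rep(names(g), sizes)))
    oracle <- TukeyHSD(aov(y ~ f, df))$f[, "p adj"]
    expect_lt(max(abs(mine[c("a-b", "a-c", "b-c")] -
                      oracle[c("b-a", "c-a", "c-b")])), 1e-3)
  }
})

test_that("Tukey HSD handles identical and strongly separated groups", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 7))
  p <- tukey_hsd(g)
  expect_equal(unname(p["a-b"]), 1, tolerance = 1e-12)
  expect_lt(p["a-c"], 0.01)
  # control vs iNPH effect size ~2.6 SD with n = 100 each: overwhelming
  set.seed(55)
  big <- list(control = rnorm(100, -2.15, 0.1), iNPH = rnorm(100, -1.89, 0.1),
              PD = rnorm(100, -2.10, 0.1))
  expect_lt(tukey_hsd(big)["control-iNPH"], 1e-7)
})

test_that("group means average trials as independent units", {
  idx <- data.frame(keypoint = rep("head", 5),
                    group = c("a", "a", "b", "b", "b"),
                    alpha = c(-2.0, -2.2, -1.8, -1.9, -2.0))
  m <- group_means(idx)
  expect_equal(m["head", "a"], -2.1)
  expect_equal(m["head", "b"], -1.9)
  idx_bad <- data.frame(keypoint = c("head", "neck"), group = c("a", "a"),
                        alpha = c(-2, -2))
  expect_error(group_means(rbind(idx, idx_bad[2, ])), "empty group")
})

test_that("cohort table reproduces generation targets and layout", {
  trials <- simulate_cohort(n_trials = c(iNPH = 3L, PD = 3L, control = 3L),
                            alpha_sd = 0, mode = "deterministic_amplitude",
                            seed = 2)
  co <- fluct_cohort(trials)
  tab <- summary(co)
  expect_equal(nrow(tab), 26L)
  ref <- published_cohort_means()
  refo <- ref[match(tab$keypoint, ref$keypoint), ]
  expect_lt(max(abs(tab$mean_iNPH - refo$inph)), 1e-6)
  expect_lt(max(abs(tab$mean_PD - refo$pd)), 1e-6)
  expect_lt(max(abs(tab$mean_control - refo$control)), 1e-6)
  # row layout mirrors the reference: same block structure and ordering rule
  expect_identical(tab$keypoint, refo$keypoint)
  expect_equal(ordering_count(co), 26L)
  # star flags are a pure function of the iNPH-PD p-value at the level
  expect_identical(tab$star, tab$p_iNPH_PD < co$level)
  expect_true(all(tab$anova_p >= 0 & tab$anova_p <= 1))
})

test_that("subject-level aggregation and Holm adjustment are available", {
  trials <- simulate_cohort(n_trials = c(iNPH = 4L, PD = 4L, control = 4L),
                            n_subjects = c(iNPH = 2L, PD = 2L, control = 2L),
                            alpha_sd = 0.1, mode = "deterministic_amplitude",
                            seed = 6)
  co_t <- fluct_cohort(trials)
  co_s <- fluct_cohort(trials, unit = "subject")
  expect_equal(nrow(summary(co_s)), 26L)
  # subject mode pools each subject's trials first
  expect_equal(length(unique(co_s$indices$subject_id)), 6L)
  co_h <- fluct_cohort(trials, p_adjust = "holm")
  expect_true(all(co_h$table$p_iNPH_PD >= co_t$table$p_iNPH_PD - 1e-12))
})

test_that("two labelled groups fall back to the pooled two-sample comparison", {
  trials <- simulate_cohort(n_trials = c(iNPH = 4L, control = 4L),
                            alpha = list(iNPH = "iNPH", control = "control"),
                            alpha_sd = 0.1, mode = "deterministic_amplitude",
                            seed = 23)
  co <- fluct_cohort(trials)
  tab <- summary(co)
  expect_equal(nrow(tab), 26L)
  # one-way ANOVA on 2 groups == pooled-variance t-test
  sub <- co$indices[co$indices$keypoint == "head", ]
  tt <- t.test(alpha ~ group, sub, var.equal = TRUE)
  expect_equal(tab$anova_p[tab$keypoint == "head"], tt$p.value,
               tolerance = 1e-10)
  expect_true(all(is.na(tab$star)))             # no iNPH-PD contrast
})

test_that("ineligible trials are dropped with a warning, not an error", {
  trials <- simulate_cohort(n_trials = c(iNPH = 2L, PD = 2L, control = 2L),
                            alpha_sd = 0, mode = "deterministic_amplitude",
                            seed = 3)
  trials[[7]] <- simulate_trial(n_frames = 100L, seed = 1, group = "control")
  expect_warning(co <- fluct_cohort(trials), "ineligible")
  expect_equal(co$n_trials, 6L)
  expect_equal(co$n_dropped, 1L)
})
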
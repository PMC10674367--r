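#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA of k independent groups; the p-value comes from the
#' F distribution with (k - 1, N - k) degrees of freedom. Degenerate inputs
#' are resolved explicitly: all observations identical gives F = 0, p = 1;
#' zero within-group variance with unequal group means gives F = Inf, p = 0.
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups, >= 2
#'   observations each).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @examples
#' one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))$F   # 4
#' @export
one_way_anova <- function(samples) {
  .check_groups(samples)
  n <- lengths(samples)
  k <- length(samples)
  N <- sum(n)
  m <- vapply(samples, mean, numeric(1))
  grand <- sum(unlist(samples)) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (.all_equal_numerically(unlist(samples)))
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons after one-way ANOVA, using the studentized
#' range distribution with the pooled within-group variance and Tukey-Kramer
#' standard errors for unbalanced group sizes — the same adjusted p-values
#' produced by `TukeyHSD(aov(...))`. With zero pooled variance, a pair with
#' equal means gets p = 1 and unequal means p = 0.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @return Named numeric vector of adjusted p-values, one per unordered pair,
#'   named `"a-b"`.
#' @export
tukey_hsd <- function(samples) {
  .check_groups(samples)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  n <- lengths(samples)
  k <- length(samples)
  df2 <- sum(n) - k
  m <- vapply(samples, mean, numeric(1))
  msw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), numeric(1))) / df2
  degenerate <- .all_equal_numerically(unlist(samples))
  pairs <- utils::combn(names(samples), 2)
  p <- apply(pairs, 2, function(pr) {
    if (degenerate) return(1)
    diffm <- abs(m[[pr[1]]] - m[[pr[2]]])
    if (msw == 0) return(if (diffm == 0) 1 else 0)
    se <- sqrt(msw / 2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    stats::ptukey(diffm / se, k, df2, lower.tail = FALSE)
  })
  stats::setNames(p, apply(pairs, 2, paste, collapse = "-"))
}

# Values identical to working precision: group comparison on residuals at
# rounding-error scale (~1e-14 relative) would be numerically meaningless, so
# such samples are treated as exactly identical (F = 0, all pairwise p = 1).
.all_equal_numerically <- function(x, tol = 1e-10) {
  diff(range(x)) <= tol * max(1, abs(mean(x)))
}

.check_groups <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(lengths(samples) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (!all(vapply(samples, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite values in groups", call. = FALSE)
  invisible(samples)
}

#' Per-keypoint, per-group mean fluctuation indices
#'
#' @param indices Long data frame of per-trial indices (as returned by
#'   [fluctuation_indices()], row-bound over trials) with columns `keypoint`,
#'   `group`, `alpha`.
#' @return Matrix of means, keypoints x groups.
#' @export
group_means <- function(indices) {
  stopifnot(all(c("keypoint", "group", "alpha") %in% names(indices)))
  tab <- tapply(indices$alpha, list(indices$keypoint, indices$group), mean)
  if (anyNA(tab)) stop("empty group for some keypoint", call. = FALSE)
  tab
}

#' Cohort-level analysis of fluctuation indices
#'
#' Fits [fluct_fit()] to every trial and summarizes the cohort per keypoint:
#' group means, one-way ANOVA across groups, Tukey HSD pairwise p-values, and
#' a significance flag for the iNPH-vs-PD contrast at `level`. Rows are
#' ordered in upper/lower x trunk/limb blocks, ascending in the absolute
#' control-group mean within each block — the layout of the published
#' reference table.
#'
#' The unit of analysis defaults to the trial, replicating the published
#' design in which patients contribute several trials on different days.
#' `unit = "subject"` first averages each subject's trials, trading fidelity
#' for independence of the analysis units.
#'
#' @param trials List of [motion_trial()] objects (or of `fluct_fit` objects,
#'   which are used as-is). Trials with fewer frames than the analysis window
#'   are dropped with a warning.
#' @param unit `"trial"` (default) or `"subject"`.
#' @param p_adjust `"none"` (default, as published) or `"holm"` across the 26
#'   keypoints within each pairwise contrast.
#' @param level Significance level for the star flag (default 0.05).
#' @param ... Passed to [fluct_fit()].
#' @return Object of class `fluct_cohort` with components `table` (one row
#'   per keypoint), `indices` (per-trial long table), `groups`, `unit`,
#'   `level`, `n_dropped`. Methods: `print`, `summary` (returns `table`),
#'   `plot` (per-position profile of the group means).
#' @examples
#' trials <- simulate_cohort(n_trials = c(iNPH = 3, PD = 3, control = 3),
#'                           alpha_sd = 0, mode = "deterministic_amplitude",
#'                           seed = 1)
#' co <- fluct_cohort(trials)
#' head(summary(co), 3)
#' @export
fluct_cohort <- function(trials, unit = c("trial", "subject"),
                         p_adjust = c("none", "holm"), level = 0.05, ...) {
  unit <- match.arg(unit)
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(trials), length(trials) >= 1L)
  fits <- list()
  dropped <- character()
  for (tr in trials) {
    if (inherits(tr, "fluct_fit")) { fits[[length(fits) + 1L]] <- tr; next }
    f <- tryCatch(fluct_fit(tr, ...), error = function(e) e)
    if (inherits(f, "error")) dropped <- c(dropped, conditionMessage(f))
    else fits[[length(fits) + 1L]] <- f
  }
  if (length(dropped) > 0)
    warning(length(dropped), " ineligible trial(s) dropped: ",
            paste(dropped, collapse = "; "), call. = FALSE)
  if (length(fits) == 0L) stop("no eligible trials", call. = FALSE)
  indices <- do.call(rbind, lapply(fits, summary))

  agg <- if (unit == "subject") {
    a <- stats::aggregate(alpha ~ subject_id + group + keypoint, indices, mean)
    a
  } else indices
  groups <- intersect(c("iNPH", "PD", "control"), unique(agg$group))
  if (length(groups) == 0L) groups <- unique(agg$group)
  if (length(groups) < 2L)
    stop("cohort comparison needs at least 2 labelled groups", call. = FALSE)

  reg <- keypoint_registry()
  reg <- reg[reg$is_target, ]
  rows <- lapply(reg$name, function(k) {
    sub <- agg[agg$keypoint == k & agg$group %in% groups, ]
    samples <- lapply(groups, function(g) sub$alpha[sub$group == g])
    names(samples) <- groups
    av <- one_way_anova(samples)
    tk <- tukey_hsd(samples)
    means <- vapply(samples, mean, numeric(1))
    row <- data.frame(keypoint = k,
                      level = reg$level[reg$name == k],
                      region = reg$region[reg$name == k],
                      stringsAsFactors = FALSE)
    for (g in groups) row[[paste0("mean_", g)]] <- means[[g]]
    row$anova_F <- av$F
    row$anova_p <- av$p
    for (nm in names(tk)) row[[paste0("p_", gsub("-", "_", nm))]] <- tk[[nm]]
    row
  })
  tab <- do.call(rbind, rows)

  pair_cols <- grep("^p_", names(tab), value = TRUE)
  if (p_adjust == "holm")
    for (cc in pair_cols) tab[[cc]] <- stats::p.adjust(tab[[cc]], "holm")
  star_col <- intersect(c("p_iNPH_PD", "p_PD_iNPH"), names(tab))
  tab$star <- if (length(star_col) == 1L) tab[[star_col[1]]] < level else NA

  # block order: upper-trunk, upper-limb, lower-trunk, lower-limb; within a
  # block, ascending |control mean| (registry order when no control group)
  block <- match(paste(tab$level, tab$region),
                 c("upper trunk", "upper limb", "lower trunk", "lower limb"))
  within <- if ("mean_control" %in% names(tab)) abs(tab$mean_control)
            else seq_len(nrow(tab))
  tab <- tab[order(block, within), ]
  rownames(tab) <- NULL

  structure(list(table = tab, indices = indices, groups = groups,
                 unit = unit, level = level, p_adjust = p_adjust,
                 n_trials = length(fits), n_dropped = length(dropped)),
            class = "fluct_cohort")
}

#' @export
summary.fluct_cohort <- function(object, ...) object$table

#' @export
print.fluct_cohort <- function(x, ...) {
  cat(sprintf("<fluct_cohort> %d trials, groups: %s (unit = %s)\n",
              x$n_trials, paste(x$groups, collapse = ", "), x$unit))
  if (x$n_dropped > 0) cat(sprintf("  %d ineligible trial(s) dropped\n",
                                   x$n_dropped))
  if (!all(is.na(x$table$star)))
    cat(sprintf("  %d of %d keypoints significant for iNPH vs PD at %g%%\n",
                sum(x$table$star), nrow(x$table), 100 * x$level))
  mcols <- grep("^mean_", names(x$table), value = TRUE)
  cat("  group means (across keypoints):\n")
  for (m in mcols)
    cat(sprintf("    %-12s %.3f\n", sub("mean_", "", m), mean(x$table[[m]])))
  invisible(x)
}

#' Per-position profile plot of group-mean fluctuation indices
#'
#' Draws one line per group over the 26 ordered body positions (table row
#' order), the cohort analogue of a per-position fluctuation profile.
#'
#' @param x A `fluct_cohort`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fluct_cohort <- function(x, ...) {
  mcols <- grep("^mean_", names(x$table), value = TRUE)
  y <- as.matrix(x$table[, mcols])
  graphics::matplot(seq_len(nrow(y)), y, type = "l", lty = 1:3, col = 1:3,
                    xlab = "body position (table order)",
                    ylab = "mean fluctuation index", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(nrow(y)), labels = x$table$keypoint,
                 las = 2, cex.axis = 0.6)
  graphics::legend("bottomright", legend = sub("mean_", "", mcols),
                   lty = 1:3, col = 1:3, bty = "n")
  invisible(x)
}

#' Count keypoints with strictly ordered group magnitudes
#'
#' Counts body positions where the absolute mean fluctuation index is
#' strictly smallest in iNPH, intermediate in PD and largest in controls —
#' i.e. |iNPH| < |PD| < |control|, the whole-body ordering reported for the
#' clinical cohorts.
#'
#' @param x A `fluct_cohort`, its summary table (columns `mean_iNPH`,
#'   `mean_PD`, `mean_control`), or a reference table with columns `inph`,
#'   `pd`, `control` (as from [published_cohort_means()]).
#' @return Integer count (0 to the number of rows).
#' @examples
#' ordering_count(published_cohort_means())   # 26
#' @export
ordering_count <- function(x) {
  if (inherits(x, "fluct_cohort")) x <- x$table
  stopifnot(is.data.frame(x))
  if (all(c("mean_iNPH", "mean_PD", "mean_control") %in% names(x))) {
    i <- abs(x$mean_iNPH); p <- abs(x$mean_PD); c <- abs(x$mean_control)
  } else if (all(c("inph", "pd", "control") %in% names(x))) {
    i <- abs(x$inph); p <- abs(x$pd); c <- abs(x$control)
  } else stop("no group mean columns found", call. = FALSE)
  sum(i < p & p < c)
}
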
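# Shared fixtures built in code.

# A minimal hand-built trial: navel fixed at the origin, every other keypoint
# at a constant offset, optionally perturbed per frame.
make_static_trial <- function(n = 128L, offset = c(3, 4, 0), fps = 30,
                              group = "unknown") {
  reg <- keypoint_registry()
  coords <- array(0, dim = c(n, 27L, 3L),
                  dimnames = list(NULL, reg$name, c("x", "y", "z")))
  for (k in reg$name[reg$is_target])
    coords[, k, ] <- matrix(offset, n, 3, byrow = TRUE)
  motion_trial(coords, fps = fps, group = group, subject_id = "static")
}

# Independent brute-force oracle for the stable-window search: scan every
# admissible start and minimize var(diff(window)) directly.
oracle_stable_start <- function(x, length = 128L, edge_trim = 30L) {
  starts <- (edge_trim + 1L):(base::length(x) - edge_trim - length + 1L)
  score <- sapply(starts, function(s) stats::var(diff(x[s:(s + length - 1L)])))
  starts[which.min(score)]
}

# Estimate the slope of an arbitrary series through the package pipeline.
pipeline_slope <- function(x, fs = 30) {
  fit_loglog(psd_periodogram(x, fs = fs))$alpha
}
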
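#' Build and validate a pipeline run configuration
#'
#' A run configuration drives the simulate/analyze/report pipeline. It can be
#' given as a named list or as a path to a YAML/JSON file; unspecified fields
#' take the defaults below, and invariants are checked eagerly so a bad
#' configuration fails before any work is done.
#'
#' Fields (defaults in parentheses): `out_dir` (`"gaitfluct_run"`), `seed`
#' (1), `level` (0.05), `window` (`"stable"`), `window_length` (128),
#' `edge_trim` (30), `f_min`/`f_max` (NULL: all bins), `unit` (`"trial"`),
#' `p_adjust` (`"none"`), and a `cohort` block with the simulator arguments of
#' [simulate_cohort()] (`n_trials`, `alpha_sd`, `mode`, `n_frames`, `fps`,
#' `noise_rms`, `cadence_hz`, `cadence_amp`).
#'
#' @param config Named list, path to a YAML/JSON file, or NULL for defaults.
#' @return Validated configuration list of class `gait_config`.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  config <- config %||% list()
  stopifnot(is.list(config))
  def <- list(out_dir = "gaitfluct_run", seed = 1L, level = 0.05,
              window = "stable", window_length = 128L, edge_trim = 30L,
              f_min = NULL, f_max = NULL, unit = "trial", p_adjust = "none",
              cohort = list(n_trials = c(iNPH = 117L, PD = 56L, control = 184L),
                            alpha_sd = 0.15, mode = "stochastic",
                            n_frames = 128L, fps = 30, noise_rms = 0.01,
                            cadence_hz = 1, cadence_amp = 0))
  cfg <- utils::modifyList(def, config)
  cfg$cohort <- utils::modifyList(def$cohort, config$cohort %||% list())
  cfg$cohort$n_trials <- unlist(cfg$cohort$n_trials)
  if (cfg$window_length %% 2L != 0L || cfg$window_length < 8L)
    stop("config error: window_length must be even and >= 8", call. = FALSE)
  if (cfg$level <= 0 || cfg$level >= 1)
    stop("config error: level must lie in (0, 1)", call. = FALSE)
  nyq <- cfg$cohort$fps / 2
  fmin <- cfg$f_min %||% 0
  fmax <- cfg$f_max %||% nyq
  if (!(fmin >= 0 && fmin < fmax && fmax <= nyq))
    stop("config error: need 0 <= f_min < f_max <= Nyquist (", nyq, " Hz)",
         call. = FALSE)
  if (any(cfg$cohort$n_trials < 2L))
    stop("config error: every group needs at least 2 trials", call. = FALSE)
  class(cfg) <- c("gait_config", "list")
  cfg
}

# md5 of the canonical JSON form of the config: a stable run fingerprint.
# The output location is not part of the fingerprint — two runs of the same
# spec into different directories are the same run.
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(cfg) {
  sprintf("#gaitfluct=%s seed=%s config=%s",
          as.character(utils::packageVersion("gaitfluct")),
          cfg$seed, .config_hash(cfg))
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort, writes one CSV trial file per
#' trial under `<out_dir>/trials/` and a `manifest.json` recording counts,
#' seed, the full cohort spec and a config fingerprint. Deterministic: the
#' same configuration (including seed) produces byte-identical files.
#'
#' @param config Anything accepted by [run_config()].
#' @return Invisibly, a list with `trial_paths` and `manifest_path`.
#' @export
pipeline_simulate <- function(config = NULL) {
  cfg <- run_config(config)
  dir.create(file.path(cfg$out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  trials <- do.call(simulate_cohort, c(cfg$cohort, list(seed = cfg$seed)))
  paths <- vapply(trials, function(tr) {
    p <- file.path(cfg$out_dir, "trials", paste0(tr$trial_id, ".csv"))
    write_trial(tr, p, format = "csv")
    p
  }, character(1))
  manifest <- list(package = "gaitfluct",
                   version = as.character(utils::packageVersion("gaitfluct")),
                   seed = cfg$seed, config_hash = .config_hash(cfg),
                   cohort = cfg$cohort,
                   n_trials_written = length(paths),
                   trials = basename(paths))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(trial_paths = paths, manifest_path = mp))
}

#' Analyze trial files into per-trial indices and a cohort table
#'
#' Loads every trial file in `input_dir` (CSV or JSON), logs one line per
#' trial with its eligibility decision, fits fluctuation indices to the
#' eligible trials and writes `indices.csv` (one row per trial x keypoint).
#' When at least two labelled groups are present it also builds the cohort
#' table and writes `cohort_table.csv` and `cohort_table.json` (the latter
#' with the upper/lower x trunk/limb block structure for plotting);
#' otherwise the cohort stage is skipped with a warning.
#'
#' @param config Anything accepted by [run_config()].
#' @param input_dir Directory of trial files; default `<out_dir>/trials`.
#' @param quiet Suppress per-trial log lines.
#' @return Invisibly, a list with `indices` (data frame), `cohort`
#'   (`fluct_cohort` or NULL) and the output paths.
#' @export
pipeline_analyze <- function(config = NULL, input_dir = NULL, quiet = FALSE) {
  cfg <- run_config(config)
  input_dir <- input_dir %||% file.path(cfg$out_dir, "trials")
  files <- list.files(input_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no trial files found in ", input_dir, call. = FALSE)
  log <- function(...) if (!quiet) message(sprintf(...))
  fits <- list()
  indices <- list()
  for (fp in sort(files)) {
    tr <- read_trial(fp)
    if (!is_eligible(tr, cfg$window_length)) {
      log("trial %-16s INELIGIBLE (%d frames < %d)", tr$trial_id,
          n_frames(tr), cfg$window_length)
      next
    }
    fit <- fluct_fit(tr, window = cfg$window,
                     window_length = cfg$window_length,
                     edge_trim = cfg$edge_trim,
                     f_min = cfg$f_min, f_max = cfg$f_max)
    log("trial %-16s ok (group=%s)", tr$trial_id, tr$group)
    fits[[length(fits) + 1L]] <- fit
    indices[[length(indices) + 1L]] <- summary(fit)
  }
  if (length(fits) == 0L) stop("no eligible trials", call. = FALSE)
  idx <- do.call(rbind, indices)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  idx_path <- file.path(cfg$out_dir, "indices.csv")
  writeLines(.provenance(cfg), idx_path)
  suppressWarnings(utils::write.table(idx, idx_path, sep = ",", append = TRUE,
                                      row.names = FALSE, quote = FALSE))
  labelled <- unique(idx$group[idx$group != "unknown"])
  cohort <- NULL
  paths <- list(indices = idx_path)
  if (length(labelled) >= 2L) {
    cohort <- fluct_cohort(fits, unit = cfg$unit, p_adjust = cfg$p_adjust,
                           level = cfg$level)
    tab_path <- file.path(cfg$out_dir, "cohort_table.csv")
    writeLines(.provenance(cfg), tab_path)
    suppressWarnings(utils::write.table(cohort$table, tab_path, sep = ",",
                                        append = TRUE, row.names = FALSE,
                                        quote = FALSE))
    blocks <- split(cohort$table,
                    paste(cohort$table$level, cohort$table$region))
    jsonlite::write_json(
      list(provenance = .provenance(cfg), groups = cohort$groups,
           blocks = blocks),
      file.path(cfg$out_dir, "cohort_table.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$cohort_table <- tab_path
  } else {
    warning("fewer than 2 labelled groups: cohort table skipped",
            call. = FALSE)
  }
  invisible(list(indices = idx, cohort = cohort, paths = paths))
}

#' Summarize a cohort table into report artifacts
#'
#' From a cohort table (a `fluct_cohort`, its summary data frame, the
#' `cohort_table.csv` written by [pipeline_analyze()], or a reference-style
#' table like [published_cohort_means()]) writes: `profile.csv` — the three
#' group-mean series over the 26 ordered positions, for per-position profile
#' plots; `starred.csv` — the positions significant for iNPH vs PD, for
#' body-map figures; and returns the strict |iNPH| < |PD| < |control|
#' ordering count.
#'
#' @param table Cohort table in any of the accepted forms.
#' @param config Anything accepted by [run_config()] (used for `out_dir`).
#' @return Invisibly, a list with `profile` (data frame), `starred`
#'   (character vector), `ordering_count` and output paths.
#' @export
pipeline_report <- function(table, config = NULL) {
  cfg <- run_config(config)
  if (inherits(table, "fluct_cohort")) table <- table$table
  if (is.character(table)) {
    if (!file.exists(table)) stop("no cohort table at ", table, call. = FALSE)
    table <- utils::read.csv(table, comment.char = "#",
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  if (all(c("inph", "pd", "control") %in% names(table))) {
    # reference-style columns
    table$mean_iNPH <- table$inph
    table$mean_PD <- table$pd
    table$mean_control <- table$control
    if (!"star" %in% names(table)) table$star <- table$starred
  }
  mcols <- grep("^mean_", names(table), value = TRUE)
  if (length(mcols) == 0L) stop("no group mean columns in table", call. = FALSE)
  profile <- table[, c("keypoint", "level", "region", mcols)]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(cfg$out_dir, "profile.csv")
  writeLines(.provenance(cfg), pp)
  suppressWarnings(utils::write.table(profile, pp, sep = ",", append = TRUE,
                                      row.names = FALSE, quote = FALSE))
  starred <- if ("star" %in% names(table))
    table$keypoint[which(as.logical(table$star))] else character()
  sp <- file.path(cfg$out_dir, "starred.csv")
  writeLines(c(.provenance(cfg), "keypoint", starred), sp)
  oc <- ordering_count(table)
  invisible(list(profile = profile, starred = starred, ordering_count = oc,
                 paths = list(profile = pp, starred = sp)))
}
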
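#' Configuration for a full pipeline run
#'
#' @param seed master integer seed.
#' @param n_per_group participants per arm (default 36).
#' @param effect an [effect_config()] (or path to a YAML file holding one).
#' @param fs sampling rate in Hz (default 10).
#' @param block_s block duration in seconds (default 30, five R-V-R-V-R
#'   blocks).
#' @param cutoff,order low-pass filter settings.
#' @param n_perm permutations per test (default 10000).
#' @param k cross-validation folds (default 5).
#' @param direction regression direction, see [perm_regression()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, n_per_group = 36, effect = effect_config(),
                       fs = 10, block_s = 30, cutoff = 0.1, order = 4,
                       n_perm = 10000, k = 5,
                       direction = "change_on_brain", out_dir = NULL) {
  if (missing(seed)) stop("`seed` is required")
  if (is.character(effect)) {
    if (!file.exists(effect)) stop("effect config file not found: ", effect)
    effect <- read_effect_config(effect)
  }
  stopifnot(inherits(effect, "effect_config"))
  structure(
    list(seed = as.integer(seed), n_per_group = n_per_group, effect = effect,
         fs = fs, block_s = block_s, cutoff = cutoff, order = order,
         n_perm = n_perm, k = k, direction = direction, out_dir = out_dir),
    class = "run_config"
  )
}

write_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline: simulate, preprocess, analyse, cross-validate
#'
#' Orchestrates the four stages as one reproducible run: cohort and
#' recording simulation, fNIRS preprocessing into per-participant activity
#' scalars, the three permutation analyses (baseline activity group
#' comparison; change-score group comparisons; activity-change regressions),
#' and the left-vs-right cross-validated prediction comparison. Every
#' stage's seed derives deterministically from `config$seed`, so the same
#' config reproduces the same tables byte for byte; the manifest written
#' alongside the tables records everything needed to re-run.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage-boundary messages.
#' @return (invisibly) list with `cohort`, `recordings`, `activity`,
#'   `baseline`, `change`, `regression`, `cv`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 5L)
  schedule <- block_schedule(c("rest", "game", "rest", "game", "rest"),
                             rep(config$block_s, 5L))

  stage <- "simulate"
  result <- tryCatch({
    cohort <- make_cohort(config$n_per_group, config$effect, seed = seeds[1])
    say("[simulate] %d participants (%d per arm)",
        nrow(cohort$participants), config$n_per_group)
    recordings <- simulate_cohort_recordings(cohort, fs = config$fs,
                                             schedule = schedule)
    say("[simulate] %d recordings of %d samples", length(recordings),
        length(recordings[[1]]$deep))

    stage <- "preprocess"
    activity <- preprocess_set(recordings, cutoff = config$cutoff,
                               order = config$order)
    say("[preprocess] %d activity estimates", nrow(activity))

    stage <- "analyze"
    baseline <- baseline_activity_ancova(cohort$participants, activity,
                                         n_perm = config$n_perm,
                                         seed = seeds[2])
    change <- change_score_ancova(cohort$participants,
                                  n_perm = config$n_perm, seed = seeds[3])
    regression <- activity_change_regression(
      cohort$participants, activity, direction = config$direction,
      n_perm = config$n_perm, seed = seeds[4]
    )
    say("[analyze] %d baseline rows, %d change rows, %d regression rows",
        nrow(baseline), nrow(change), nrow(regression))

    stage <- "crossval"
    cv <- cross_validate_all(cohort$participants, activity, k = config$k,
                             seed = seeds[5])
    say("[crossval] %d rows", nrow(cv))

    list(cohort = cohort, recordings = recordings, activity = activity,
         baseline = baseline, change = change, regression = regression,
         cv = cv)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package = "nirscog",
    version = as.character(utils::packageVersion("nirscog")),
    seed = config$seed, stage_seeds = seeds,
    n_per_group = config$n_per_group, fs = config$fs,
    block_s = config$block_s, cutoff = config$cutoff, order = config$order,
    n_perm = config$n_perm, k = config$k, direction = config$direction
  )
  result$manifest <- manifest

  if (!is.null(dir)) {
    write_cohort_csv(result$cohort, file.path(dir, "participants.csv"))
    write_table(result$activity, dir, "activity.csv")
    write_table(result$baseline, dir, "baseline_ancova.csv")
    write_table(result$change, dir, "change_ancova.csv")
    write_table(result$regression, dir, "regression_results.csv")
    write_table(result$cv, dir, "cv_results.csv")
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("[write] tables and manifest in %s", dir)
  }
  invisible(result)
}
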
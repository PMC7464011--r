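#' Construct a dual source-detector recording
#'
#' One hemisphere's shallow (1 cm source-detector pair, scalp/skull) and deep
#' (3 cm pair, scalp + cortex) total-hemoglobin time series, with sampling
#' rate and block schedule.
#'
#' @param id participant id.
#' @param side `"left"` or `"right"`.
#' @param fs sampling rate in Hz.
#' @param shallow,deep numeric series of equal length
#'   `round(schedule_duration(schedule) * fs)`.
#' @param schedule a [block_schedule()].
#' @param true_amplitude simulation ground truth neural amplitude, or `NA`
#'   for real data.
#' @return A `nirs_recording` object.
#' @export
nirs_recording <- function(id, side, fs, shallow, deep, schedule,
                           true_amplitude = NA_real_) {
  side <- match.arg(side, c("left", "right"))
  if (!inherits(schedule, "block_schedule")) stop("invalid `schedule`")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  n_expect <- round(schedule_duration(schedule) * fs)
  if (length(shallow) != length(deep)) {
    stop("shallow and deep series must have equal length")
  }
  if (length(deep) != n_expect) {
    stop(sprintf("series length %d does not match schedule x fs = %d",
                 length(deep), n_expect))
  }
  structure(
    list(id = id, side = side, fs = fs, shallow = as.numeric(shallow),
         deep = as.numeric(deep), schedule = schedule,
         true_amplitude = true_amplitude),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("nirs_recording: %s/%s, %d samples @ %g Hz%s\n",
              x$id, x$side, length(x$deep), x$fs,
              if (is.na(x$true_amplitude)) ""
              else sprintf(", true amplitude %.3f", x$true_amplitude)))
  invisible(x)
}

# AR(1) systemic wander with burn-in; returns zeros when sd == 0.
ar1_series <- function(n, phi, sd, burn = 500L) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n + burn, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))[burn + seq_len(n)]
}

#' Simulate one dual source-detector recording
#'
#' Generative model: the deep channel is the neural response (game-block
#' boxcar convolved with the canonical HRF, unit peak, scaled by
#' `amplitude`) plus a coupling-weighted copy of the systemic signal, a
#' linear drift and white noise; the shallow channel carries the same
#' systemic signal with its own drift and noise but no neural component.
#' The systemic signal shared by both channels is a slow Mayer-wave
#' sinusoid, a cardiac-band sinusoid (random phases) and AR(1) wander.
#'
#' @param amplitude true neural amplitude (a.u., peak block response).
#' @param fs sampling rate in Hz (> 0).
#' @param schedule a [block_schedule()] with at least one game block.
#' @param noise an [effect_config()] supplying the noise parameters.
#' @param seed integer seed.
#' @param id,side metadata stored on the recording.
#' @return A [nirs_recording()] with `true_amplitude = amplitude`.
#' @export
simulate_recording <- function(amplitude, fs, schedule,
                               noise = effect_config(), seed,
                               id = "sim", side = "left") {
  if (missing(seed)) stop("`seed` is required")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  if (!inherits(schedule, "block_schedule") || nrow(schedule) == 0) {
    stop("`schedule` must be a non-empty block_schedule")
  }
  stopifnot(inherits(noise, "effect_config"))
  n <- round(schedule_duration(schedule) * fs)
  t <- (seq_len(n) - 1) / fs
  reg <- neural_regressor(schedule, fs, n)

  with_seed(seed, {
    phases <- stats::runif(2, 0, 2 * pi)
    systemic <- noise$mayer_amp * sin(2 * pi * noise$mayer_freq * t + phases[1]) +
      noise$cardiac_amp * sin(2 * pi * noise$cardiac_freq * t + phases[2]) +
      ar1_series(n, noise$ar_phi, noise$ar_sd)
    coupling <- stats::rnorm(1, noise$coupling_mean, noise$coupling_sd)
    slopes <- stats::rnorm(2, 0, noise$drift_sd)
    eps_d <- stats::rnorm(n, 0, noise$noise_sd)
    eps_s <- stats::rnorm(n, 0, noise$noise_sd)
    deep <- amplitude * reg + coupling * systemic + slopes[1] * t + eps_d
    shallow <- systemic + slopes[2] * t + eps_s
    nirs_recording(id, side, fs, shallow, deep, schedule,
                   true_amplitude = amplitude)
  })
}

#' Simulate recordings for every participant in a cohort
#'
#' Left and right hemisphere recordings per participant, driven by the
#' cohort's stored latent amplitudes and per-participant seed substreams.
#'
#' @param cohort a `nirs_cohort` from [make_cohort()].
#' @param fs sampling rate in Hz.
#' @param schedule a [block_schedule()].
#' @return list of [nirs_recording()] objects (two per participant).
#' @export
simulate_cohort_recordings <- function(cohort, fs = 10,
                                       schedule = default_schedule()) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  amp <- cohort$amplitudes
  recs <- vector("list", 2L * nrow(amp))
  for (i in seq_len(nrow(amp))) {
    for (s in c("left", "right")) {
      recs[[2L * (i - 1L) + (s == "right") + 1L]] <- simulate_recording(
        amplitude = amp[[s]][i], fs = fs, schedule = schedule,
        noise = cohort$config, seed = cohort$rec_seeds[i, s],
        id = amp$id[i], side = s
      )
    }
  }
  recs
}

#' Write / read a set of recordings
#'
#' `write_recordings` writes one long CSV (`id,side,t,shallow,deep`) plus a
#' JSON sidecar holding the schedule, sampling rate and, for simulated data,
#' the true amplitudes. `read_recordings` reconstructs the list of
#' [nirs_recording()] objects.
#'
#' @param recordings list of `nirs_recording` objects sharing `fs` and
#'   schedule.
#' @param dir output directory (created if missing).
#' @return `write_recordings` returns `dir` invisibly; `read_recordings` the
#'   list of recordings.
#' @export
write_recordings <- function(recordings, dir) {
  stopifnot(length(recordings) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- recordings[[1]]$fs
  sched <- recordings[[1]]$schedule
  long <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(id = r$id, side = r$side,
               t = (seq_along(r$deep) - 1) / r$fs,
               shallow = r$shallow, deep = r$deep,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "recordings.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    fs = fs,
    schedule = list(label = sched$label, start = sched$start, end = sched$end),
    true_amplitude = lapply(recordings, function(r) {
      list(id = r$id, side = r$side, amplitude = r$true_amplitude)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "recordings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  long <- utils::read.csv(file.path(dir, "recordings.csv"),
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "recordings.json"),
                              simplifyVector = TRUE)
  sched <- block_schedule(meta$schedule$label,
                          meta$schedule$end - meta$schedule$start)
  amps <- meta$true_amplitude
  key <- split(long, list(long$id, long$side), drop = TRUE)
  lapply(unname(key), function(d) {
    d <- d[order(d$t), ]
    a <- NA_real_
    if (!is.null(amps) && length(amps) > 0) {
      hit <- which(amps$id == d$id[1] & amps$side == d$side[1])
      if (length(hit) == 1) a <- as.numeric(amps$amplitude[hit])
    }
    nirs_recording(d$id[1], d$side[1], meta$fs, d$shallow, d$deep, sched,
                   true_amplitude = a)
  })
}
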
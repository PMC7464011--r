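#' Remove a linear trend
#'
#' Subtracts the ordinary least-squares straight-line fit (intercept and
#' slope) from a series, so the best-fit line of the output is the zero line.
#'
#' @param x numeric series of length >= 2.
#' @param fs sampling rate in Hz (used only to express time in seconds;
#'   the residual is invariant to the time scale).
#' @return detrended numeric series of the same length.
#' @export
detrend <- function(x, fs = 1) {
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  t <- (seq_len(n) - 1) / fs
  fit <- stats::lm.fit(cbind(1, t), x)
  as.numeric(fit$residuals)
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward, giving zero
#' phase shift — block boundaries are not displaced — and a squared
#' magnitude response (the single-pass -3 dB point becomes -6 dB). To tame
#' start-up transients the series is mean-centred and extended at both ends
#' by odd reflection before the two-pass filter, then trimmed back, so the
#' DC gain is 1 to numerical precision.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff cutoff frequency in Hz (default 0.1).
#' @param order filter order of the single pass (default 4).
#' @return filtered series of the same length.
#' @export
lowpass <- function(x, fs, cutoff = 0.1, order = 4) {
  if (cutoff <= 0 || fs <= 0) stop("`fs` and `cutoff` must be positive")
  if (cutoff >= fs / 2) stop("`cutoff` must be below the Nyquist frequency fs/2")
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1, ceiling(12 * fs / cutoff))
  ext <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))[pad + seq_len(n)]
  y + mu
}

#' Short-separation (dual source-detector) regression
#'
#' Removes the scalp/skull component from the deep channel by regressing
#' deep on shallow (with intercept) and keeping the residual: the estimated
#' neural signal. The residual has exactly zero mean and zero sample
#' correlation with the shallow series. If the shallow series has zero
#' variance there is nothing to regress out; the deep series is mean-centred
#' instead and a warning is raised.
#'
#' @param deep,shallow numeric series of equal length >= 3.
#' @return A `neural_series`: list with `values`, plus the fitted `coef`
#'   (intercept, slope) and a `degenerate` flag.
#' @export
short_separation_regress <- function(deep, shallow) {
  n <- length(deep)
  if (length(shallow) != n) stop("deep and shallow lengths differ")
  if (n < 3) stop("need at least 3 samples")
  if (stats::var(shallow) == 0) {
    warning("shallow series has zero variance; falling back to mean-centering")
    return(structure(
      list(values = deep - mean(deep), coef = c(mean(deep), 0),
           degenerate = TRUE),
      class = "neural_series"
    ))
  }
  fit <- stats::lm.fit(cbind(1, shallow), deep)
  structure(
    list(values = as.numeric(fit$residuals),
         coef = unname(fit$coefficients), degenerate = FALSE),
    class = "neural_series"
  )
}

#' Baseline-correct a neural series against preceding rest blocks
#'
#' Subtracts, from every game-block sample, the mean of the signal over that
#' game block's immediately preceding rest block; rest-block samples have
#' their own block mean subtracted. Every game block must be preceded by a
#' rest block.
#'
#' @param values numeric series.
#' @param schedule a [block_schedule()].
#' @param fs sampling rate in Hz.
#' @return corrected numeric series of the same length.
#' @export
baseline_correct <- function(values, schedule, fs) {
  n <- length(values)
  out <- values
  for (i in seq_len(nrow(schedule))) {
    idx <- block_sample_index(schedule, i, fs, n)
    if (schedule$label[i] == "game") {
      if (i == 1L || schedule$label[i - 1L] != "rest") {
        stop("every game block must be preceded by a rest block")
      }
      ref <- mean(values[block_sample_index(schedule, i - 1L, fs, n)])
    } else {
      ref <- mean(values[idx])
    }
    out[idx] <- values[idx] - ref
  }
  out
}

#' Average the corrected signal over game blocks
#'
#' The per-participant activity scalar: the mean of the baseline-corrected
#' neural signal over all game-block samples (equivalently, per-block means
#' weighted by block sample counts). Per-block means are reported alongside.
#'
#' @param values baseline-corrected numeric series.
#' @param schedule a [block_schedule()] with at least one game block.
#' @param fs sampling rate in Hz.
#' @param id,side metadata carried to the result.
#' @return An `activity_estimate`: list with `id`, `side`, `activity`,
#'   `block_means`, `block_n`.
#' @export
block_average <- function(values, schedule, fs, id = NA_character_,
                          side = NA_character_) {
  game <- which(schedule$label == "game")
  if (length(game) == 0) stop("schedule has no game blocks")
  idx_list <- lapply(game, block_sample_index, schedule = schedule,
                     fs = fs, n = length(values))
  block_means <- vapply(idx_list, function(ix) mean(values[ix]), numeric(1))
  block_n <- lengths(idx_list)
  structure(
    list(id = id, side = side,
         activity = sum(block_means * block_n) / sum(block_n),
         block_means = block_means, block_n = block_n),
    class = "activity_estimate"
  )
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("activity_estimate: %s/%s activity %.4f (block means: %s)\n",
              x$id, x$side, x$activity,
              paste(sprintf("%.4f", x$block_means), collapse = ", ")))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order: linear detrending and zero-phase low-pass filtering of
#' both shallow and deep channels; short-separation regression of deep on
#' shallow; baseline correction against each game block's preceding rest
#' block; and averaging over game-block samples into one activity scalar.
#'
#' @param recording a [nirs_recording()].
#' @param cutoff low-pass cutoff in Hz (default 0.1).
#' @param order Butterworth order (default 4).
#' @param use_short_separation set `FALSE` to skip the shallow-channel
#'   regression (for method comparisons; the deep channel is then only
#'   mean-centred at the regression stage).
#' @return An `activity_estimate`.
#' @export
preprocess_recording <- function(recording, cutoff = 0.1, order = 4,
                                 use_short_separation = TRUE) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$fs
  deep <- lowpass(detrend(recording$deep, fs), fs, cutoff, order)
  shallow <- lowpass(detrend(recording$shallow, fs), fs, cutoff, order)
  neural <- if (use_short_separation) {
    short_separation_regress(deep, shallow)$values
  } else {
    deep - mean(deep)
  }
  corrected <- baseline_correct(neural, recording$schedule, fs)
  block_average(corrected, recording$schedule, fs,
                id = recording$id, side = recording$side)
}

#' Preprocess a set of recordings into an activity table
#'
#' @param recordings list of [nirs_recording()] objects.
#' @param ... passed to [preprocess_recording()].
#' @return data.frame with columns `id`, `side`, `activity`.
#' @export
preprocess_set <- function(recordings, ...) {
  rows <- lapply(recordings, function(r) {
    est <- preprocess_recording(r, ...)
    data.frame(id = est$id, side = est$side, activity = est$activity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read the activity table
#' @param activity data.frame `id,side,activity`.
#' @param path CSV path.
#' @return `write_activity_csv` returns `path` invisibly; `read_activity_csv`
#'   the data.frame.
#' @export
write_activity_csv <- function(activity, path) {
  utils::write.csv(activity, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
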
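#' Block schedule for a rest/game fNIRS recording
#'
#' A `block_schedule` is an ordered set of contiguous, non-overlapping blocks,
#' each labelled `"rest"` or `"game"`. The schedule must alternate rest and
#' game blocks, beginning and ending with rest, so that every game block has
#' an immediately preceding rest block to serve as its baseline.
#'
#' @param labels character vector of block labels, each `"rest"` or `"game"`.
#' @param durations numeric vector of block durations in seconds (same length
#'   as `labels`), all strictly positive.
#' @return A `block_schedule` object: a data.frame with columns `label`,
#'   `start`, `end` (seconds).
#' @examples
#' block_schedule(c("rest", "game", "rest"), c(30, 30, 30))
#' @export
block_schedule <- function(labels, durations) {
  if (length(labels) != length(durations) || length(labels) == 0L) {
    stop("`labels` and `durations` must be non-empty and of equal length")
  }
  if (!all(labels %in% c("rest", "game"))) {
    stop("block labels must be 'rest' or 'game'")
  }
  if (!all(is.finite(durations)) || any(durations <= 0)) {
    stop("block durations must be finite and positive")
  }
  if (labels[1L] != "rest" || labels[length(labels)] != "rest") {
    stop("schedule must begin and end with a rest block")
  }
  if (length(labels) > 1L && any(labels[-1L] == labels[-length(labels)])) {
    stop("rest and game blocks must alternate")
  }
  end <- cumsum(durations)
  out <- data.frame(
    label = labels,
    start = c(0, end[-length(end)]),
    end = end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("block_schedule", "data.frame")
  out
}

#' Default R-V-R-V-R schedule
#'
#' Five alternating blocks (rest, game, rest, game, rest) of equal duration,
#' 30 s each by default, for a 150 s recording.
#'
#' @param block_s duration of each block in seconds.
#' @return A [block_schedule()].
#' @export
default_schedule <- function(block_s = 30) {
  block_schedule(c("rest", "game", "rest", "game", "rest"), rep(block_s, 5L))
}

#' Total duration of a schedule in seconds
#' @param schedule a [block_schedule()].
#' @return numeric scalar, seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  schedule$end[nrow(schedule)]
}

# Sample indices of block i for a series sampled at `fs` with t_k = (k-1)/fs.
# Half-open convention: start <= t < end, so contiguous blocks partition the
# samples exactly.
block_sample_index <- function(schedule, i, fs, n) {
  t <- (seq_len(n) - 1) / fs
  which(t >= schedule$start[i] & t < schedule$end[i])
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf(
    "block_schedule: %d blocks, %.1f s total (%s)\n",
    nrow(x), x$end[nrow(x)],
    paste(ifelse(x$label == "rest", "R", "V"), collapse = "-")
  ))
  invisible(x)
}
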
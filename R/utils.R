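#' Convert a duration in seconds to a whole number of frames
#'
#' Window lengths are converted with \code{round(length * rate)}, so a 1 s
#' window at 30 Hz is exactly 30 frames. The same rule is used everywhere a
#' duration meets the frame grid.
#'
#' @param seconds duration(s) in seconds.
#' @param frameRate sampling rate in Hz.
#' @return integer vector of frame counts.
#' @export
secondsToFrames <- function(seconds, frameRate) {
  stopifnot(is.numeric(seconds), is.numeric(frameRate), frameRate > 0)
  as.integer(round(seconds * frameRate))
}

## 0-based frame index of an absolute time point; frame i covers
## [i/rate, (i+1)/rate).
timeToFrame0 <- function(t, frameRate) as.integer(round(t * frameRate))

#' Derive a reproducible per-stage seed from a single pipeline seed
#'
#' One global seed is expanded into independent per-stage seeds so that each
#' stage (scheduling, truth assignment, synthesis, null building, ...) is
#' individually reproducible. Kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage integer stage index (>= 1) or a known stage name.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
  stages <- c(schedule = 1L, truth = 2L, traces = 3L, null = 4L,
              metrics = 5L, report = 6L)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 7919) %% 2147483647)
}

## column-wise cumulative sums with a leading zero row, so that
## cs[a + 1, k] - cs[b + 1, k] is the sum of frames (b, a] of column k.
colCumsum0 <- function(m) {
  rbind(0, apply(m, 2, cumsum))
}

## stop() with a classed condition so callers/tests can distinguish
## validation, format and consistency failures.
stopTyped <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
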
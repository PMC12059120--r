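## Trial alignment, per-trial dF/F normalization, Savitzky-Golay smoothing.

.anchorColumn <- function(anchor) {
  cols <- c(stim_onset = "stim_onset_s", sound_onset = "sound_onset_s",
            sound_offset = "sound_offset_s", cue_onset = "cue_onset_s")
  if (!anchor %in% names(cols)) stopTyped("validationError", "unknown anchor: ", anchor)
  cols[[anchor]]
}

#' Cut trial-aligned snippets from a continuous recording
#'
#' Each snippet covers frames \code{[anchor - pre, anchor + post)} of its
#' trial's anchor event, converted to the frame grid with
#' \code{round(t * rate)}. All snippets have the same length; the anchor sits
#' at snippet index \code{anchorFrame(x)} (1-based).
#'
#' @param rec a \linkS4class{CalciumRecording}.
#' @param trials a \linkS4class{TrialTable} or data.frame of trials to align
#'   (all must carry the anchor event).
#' @param anchor "stim_onset", "sound_onset", "sound_offset" or "cue_onset".
#' @param pre,post window extents in seconds before/after the anchor.
#' @return a \linkS4class{TrialTensor}.
#' @export
alignTrials <- function(rec, trials, anchor = "stim_onset", pre = 2, post = 2) {
  d <- if (methods::is(trials, "TrialTable")) trialData(trials) else trials
  col <- .anchorColumn(anchor)
  tAnchor <- d[[col]]
  if (anyNA(tAnchor))
    stopTyped("validationError", sprintf(
      "trial %d lacks the %s event", d$trial_id[which(is.na(tAnchor))[1]], anchor))
  rate <- frameRate(rec)
  nPre <- secondsToFrames(pre, rate)
  nPost <- secondsToFrames(post, rate)
  a0 <- timeToFrame0(tAnchor, rate)
  lo <- a0 - nPre + 1L
  hi <- a0 + nPost
  bad <- which(lo < 1L | hi > nFrames(rec))
  if (length(bad))
    stopTyped("validationError", sprintf(
      "alignment window out of bounds for trial %d", d$trial_id[bad[1]]))
  F <- fluorescence(rec)
  vals <- array(NA_real_, dim = c(nNeurons(rec), nrow(d), nPre + nPost))
  for (j in seq_len(nrow(d)))
    vals[, j, ] <- F[, lo[j]:hi[j]]
  methods::new("TrialTensor", values = vals, t0 = nPre + 1L,
               frameRate = rate, trialIds = as.integer(d$trial_id),
               neuronIds = neuronIds(rec), anchor = anchor)
}

#' Snippet frame index of a trial event
#'
#' Maps an event (e.g. "stim_onset") of each aligned trial to its 1-based
#' frame index within the snippet of a \linkS4class{TrialTensor} /
#' \linkS4class{DffTensor}.
#'
#' @param tensor an aligned tensor.
#' @param trials the trial table (or data.frame) the tensor was cut from.
#' @param event event name as for \code{\link{alignTrials}}.
#' @return integer vector, one index per aligned trial.
#' @export
eventFrame <- function(tensor, trials, event) {
  d <- if (methods::is(trials, "TrialTable")) trialData(trials) else trials
  d <- d[match(trialIds(tensor), d$trial_id), , drop = FALSE]
  tEvent <- d[[.anchorColumn(event)]]
  tAnchor <- d[[.anchorColumn(tensor@anchor)]]
  if (anyNA(tEvent))
    stopTyped("validationError", sprintf(
      "trial %d lacks the %s event", d$trial_id[which(is.na(tEvent))[1]], event))
  tensor@t0 + as.integer(round((tEvent - tAnchor) * frameRate(tensor)))
}

#' Per-trial dF/F normalization
#'
#' \code{dF/F = (F - F0) / F0} with \code{F0} computed per trial as the mean
#' fluorescence in the 1 s window before that trial's start cue. The aligned
#' snippet must contain the full pre-cue window.
#'
#' @param aligned a \linkS4class{TrialTensor}.
#' @param trials the trial table the tensor was cut from.
#' @param baselineLen pre-cue baseline length in seconds (default 1).
#' @param eps degenerate-baseline guard: error if any F0 <= eps * median(F);
#'   default 1e-6.
#' @return a \linkS4class{DffTensor}.
#' @export
computeDff <- function(aligned, trials, baselineLen = 1, eps = 1e-6) {
  d <- if (methods::is(trials, "TrialTable")) trialData(trials) else trials
  rate <- frameRate(aligned)
  nBase <- secondsToFrames(baselineLen, rate)
  cueF <- eventFrame(aligned, trials, "cue_onset")
  if (any(cueF - nBase < 1L) || any(cueF - 1L > nFrames(aligned)))
    stopTyped("validationError",
              "snippets do not contain the pre-cue baseline window")
  vals <- tensorValues(aligned)
  n <- dim(vals)[1]; ntr <- dim(vals)[2]
  f0 <- matrix(NA_real_, n, ntr)
  for (j in seq_len(ntr))
    f0[, j] <- rowMeans(vals[, j, (cueF[j] - nBase):(cueF[j] - 1L), drop = FALSE])
  thr <- eps * stats::median(vals)
  if (any(f0 <= thr)) {
    bad <- which(f0 <= thr, arr.ind = TRUE)[1, ]
    stopTyped("validationError", sprintf(
      "degenerate baseline F0 for neuron '%s', trial %d",
      neuronIds(aligned)[bad[1]], trialIds(aligned)[bad[2]]))
  }
  dff <- sweep(sweep(vals, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  methods::new("DffTensor", values = dff, t0 = aligned@t0, frameRate = rate,
               trialIds = trialIds(aligned), neuronIds = neuronIds(aligned),
               anchor = aligned@anchor, f0 = f0)
}

#' Align one session and compute its dF/F tensor
#'
#' Convenience for the standard per-session geometry: snippets anchored at
#' the trial-start cue, 2 s before to \code{post} seconds after, then
#' per-trial dF/F.
#'
#' @param rec a \linkS4class{CalciumRecording}.
#' @param trials the full \linkS4class{TrialTable}.
#' @param session session to extract.
#' @param pre,post snippet extent around the cue, seconds.
#' @return list with \code{dff} (a \linkS4class{DffTensor}) and
#'   \code{trials} (the session's trial rows).
#' @export
sessionTensor <- function(rec, trials, session, pre = 2, post = 6) {
  d <- sessionTrials(trials, session)
  if (!nrow(d)) stopTyped("validationError", "no trials in session ", session)
  aligned <- alignTrials(rec, d, anchor = "cue_onset", pre = pre, post = post)
  list(dff = computeDff(aligned, d), trials = d)
}

## Savitzky-Golay projection matrix and the odd window-length rule:
## a duration in seconds becomes ceiling(sec * rate) frames, bumped up to the
## next odd count (an SG window must be odd and centered).
.sgWindowFrames <- function(windowSec, frameRate, order = 1) {
  n <- as.integer(ceiling(windowSec * frameRate))
  if (n %% 2L == 0L) n <- n + 1L
  max(n, order + 2L - (order %% 2L))  # at least order+1, and odd
}

## smooth each column of X (frames x series) with an order-p SG filter;
## interior by convolution with the center row, edges by the SG edge rows
## (polynomial fits to the first/last window), so polynomials up to order p
## are reproduced exactly everywhere.
.sgSmoothMatrix <- function(X, n, p = 1) {
  L <- nrow(X)
  if (n > L) stopTyped("validationError", "SG window longer than the series")
  Fm <- unclass(signal::sgolay(p = p, n = n))
  h <- (n - 1L) %/% 2L
  Y <- stats::filter(X, Fm[h + 1L, ], sides = 2)
  Y <- matrix(as.numeric(Y), nrow = L)
  Y[1:h, ] <- Fm[1:h, , drop = FALSE] %*% X[1:n, , drop = FALSE]
  Y[(L - h + 1L):L, ] <- Fm[(h + 2L):n, , drop = FALSE] %*%
    X[(L - n + 1L):L, , drop = FALSE]
  Y
}

#' Savitzky-Golay smoothing of a frame series
#'
#' First-order (local linear least-squares) smoothing over a centered
#' odd-length window; output length equals input length. Edge frames are
#' smoothed with the corresponding Savitzky-Golay edge rows (polynomial fits
#' to the first/last full window), so constants and linear ramps are
#' reproduced exactly over the whole series. A 150 ms window at 30 Hz is
#' 4.5 frames, rounded up to the nearest odd count: 5 frames.
#'
#' @param x numeric vector (one trace).
#' @param windowSec smoothing window in seconds (default 0.150).
#' @param order polynomial order (default 1).
#' @param frameRate sampling rate, Hz.
#' @return smoothed numeric vector of the same length.
#' @export
sgSmooth <- function(x, windowSec = 0.150, order = 1, frameRate = 30) {
  n <- .sgWindowFrames(windowSec, frameRate, order)
  if (n > length(x))
    stopTyped("validationError", "SG window longer than the series")
  as.numeric(.sgSmoothMatrix(matrix(x, ncol = 1), n = n, p = order))
}
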
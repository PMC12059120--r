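## Shuffle-null responsiveness classification: per neuron x session x
## stimulus window, single-trial baseline-corrected responses are compared
## against a null of identically shaped windows placed at random positions
## within the same session's trials (two-sided rank-sum, p < alpha), with
## odd/even cross-validated selection of positively modulated neurons.

## cumulative-sum representation of a dff tensor for fast window means:
## S is (frames+1) x (neurons*trials) with a leading zero row; the column of
## (neuron i, trial j) is (j-1)*N + i. sum of frames a..b of a snippet is
## S[b+1, col] - S[a, col].
.tensorCumsum <- function(tensor) {
  v <- tensorValues(tensor)
  N <- dim(v)[1]; ntr <- dim(v)[2]; f <- dim(v)[3]
  m <- matrix(aperm(v, c(3, 1, 2)), nrow = f)
  list(S = colCumsum0(m), N = N, ntr = ntr, f = f)
}

## baseline-corrected window mean at anchor frame `a` (1-based index of the
## first response frame) for given columns: mean of [a, a+nResp) minus mean
## of [a-nBase, a).
.windowDiff <- function(cs, cols, a, nResp, nBase) {
  post <- (cs$S[cbind(a + nResp, cols)] - cs$S[cbind(a, cols)]) / nResp
  pre <- (cs$S[cbind(a, cols)] - cs$S[cbind(a - nBase, cols)]) / nBase
  post - pre
}

#' Single-trial baseline-corrected stimulus responses
#'
#' For each neuron and each requested trial, the mean dF/F in the response
#' window \code{[anchor, anchor + responseLen)} minus the mean in the
#' baseline window \code{[anchor - baselineLen, anchor)}.
#'
#' @param dff a \linkS4class{DffTensor}.
#' @param trialIdx indices (into the tensor's trial dimension) of the trials
#'   to evaluate; default all.
#' @param anchorFrames 1-based snippet frame index where the response window
#'   starts, one per requested trial (recycled if length 1); defaults to the
#'   tensor's alignment anchor.
#' @param responseLen,baselineLen window lengths in seconds.
#' @return numeric matrix, neurons x trials.
#' @export
singleTrialResponses <- function(dff, trialIdx = seq_len(nTrials(dff)),
                                 anchorFrames = anchorFrame(dff),
                                 responseLen = 1, baselineLen = 1) {
  rate <- frameRate(dff)
  nResp <- secondsToFrames(responseLen, rate)
  nBase <- secondsToFrames(baselineLen, rate)
  anchorFrames <- rep_len(anchorFrames, length(trialIdx))
  if (any(anchorFrames - nBase < 1L) || any(anchorFrames + nResp - 1L > nFrames(dff)))
    stopTyped("validationError", "response/baseline window outside the snippet")
  cs <- .tensorCumsum(dff)
  N <- cs$N
  out <- matrix(NA_real_, N, length(trialIdx))
  for (j in seq_along(trialIdx)) {
    cols <- (trialIdx[j] - 1L) * N + seq_len(N)
    out[, j] <- .windowDiff(cs, cols, rep(anchorFrames[j], N), nResp, nBase)
  }
  rownames(out) <- neuronIds(dff)
  out
}

#' Build the shuffle-null distribution for every neuron of a session
#'
#' Each draw is a baseline-corrected window mean (as in
#' \code{\link{singleTrialResponses}}) at an anchor placed uniformly at
#' random within the session's trials, wherever both windows fit inside the
#' snippet. Draws are with replacement and independent across neurons.
#' True stimulus windows are not excluded by default (the literal "random
#' events from its same session" reading, conservative under true
#' responses); \code{excludeFrames} removes an index range from the anchor
#' pool for sensitivity analyses.
#'
#' @param dff a \linkS4class{DffTensor} of one session.
#' @param nDraws draws per neuron (default 1000).
#' @param trialIdx trials to draw from; default all.
#' @param responseLen,baselineLen window lengths in seconds.
#' @param excludeFrames optional integer vector of anchor frames to exclude.
#' @param seed RNG seed.
#' @return a \linkS4class{NullDistribution}.
#' @export
buildNull <- function(dff, nDraws = 1000, trialIdx = seq_len(nTrials(dff)),
                      responseLen = 1, baselineLen = 1, excludeFrames = NULL,
                      seed = 1L) {
  rate <- frameRate(dff)
  nResp <- secondsToFrames(responseLen, rate)
  nBase <- secondsToFrames(baselineLen, rate)
  if (nFrames(dff) - nResp + 1L < nBase + 1L)
    stopTyped("validationError", "session too short to place null windows")
  valid <- seq.int(nBase + 1L, nFrames(dff) - nResp + 1L)
  valid <- setdiff(valid, excludeFrames)
  if (!length(valid) || !length(trialIdx))
    stopTyped("validationError", "session too short to place null windows")
  cs <- .tensorCumsum(dff)
  N <- cs$N
  set.seed(as.integer(seed))
  vals <- matrix(NA_real_, N, nDraws)
  for (i in seq_len(N)) {
    tr <- trialIdx[sample.int(length(trialIdx), nDraws, replace = TRUE)]
    a <- valid[sample.int(length(valid), nDraws, replace = TRUE)]
    cols <- (tr - 1L) * N + i
    vals[i, ] <- .windowDiff(cs, cols, a, nResp, nBase)
  }
  rownames(vals) <- neuronIds(dff)
  methods::new("NullDistribution", values = vals, nDraws = as.integer(nDraws),
               seed = as.integer(seed))
}

#' Classify every neuron of a session against its shuffle null
#'
#' For one stimulus window (a set of trials plus per-trial anchor frames),
#' compares each neuron's single-trial responses with its null draws using
#' the two-sided rank-sum test. \code{responsive} uses all trials;
#' \code{selected} is the cross-validated cohort: the odd-trial responses
#' (1st, 3rd, ... in presentation order) must themselves differ from the
#' null (p < alpha) *and* have a positive mean, so that even-trial
#' statistics reported downstream are untouched by the selection.
#' Windows with fewer than \code{minTrials} trials are flagged
#' \code{insufficient} rather than tested.
#'
#' @param dff a \linkS4class{DffTensor} of one session.
#' @param null the session's \linkS4class{NullDistribution}.
#' @param trialIdx tensor trial indices forming the stimulus window's trials.
#' @param anchorFrames per-trial response-onset frames (see
#'   \code{\link{singleTrialResponses}}).
#' @param session,window labels stored in the output.
#' @param alpha significance level (default 0.05).
#' @param responseLen,baselineLen window lengths in seconds.
#' @param minTrials minimum trials required to test (default 5).
#' @return data.frame with one row per neuron: p-values (all and odd
#'   trials), responsive/selected flags, odd/even/all-trial means.
#' @export
classifySession <- function(dff, null, trialIdx, anchorFrames,
                            session = "session", window = "window",
                            alpha = 0.05, responseLen = 1, baselineLen = 1,
                            minTrials = 5L) {
  resp <- singleTrialResponses(dff, trialIdx, anchorFrames,
                               responseLen = responseLen,
                               baselineLen = baselineLen)
  N <- nrow(resp); ntr <- ncol(resp)
  oddIdx <- seq(1L, ntr, by = 2L)
  evenIdx <- if (ntr >= 2L) seq(2L, ntr, by = 2L) else integer(0)
  insufficient <- ntr < minTrials
  pAll <- pOdd <- rep(NA_real_, N)
  if (!insufficient) {
    nv <- nullValues(null)
    for (i in seq_len(N)) {
      pAll[i] <- rankSumTest(resp[i, ], nv[i, ])
      pOdd[i] <- rankSumTest(resp[i, oddIdx], nv[i, ])
    }
  }
  oddMean <- rowMeans(resp[, oddIdx, drop = FALSE])
  evenMean <- if (length(evenIdx)) rowMeans(resp[, evenIdx, drop = FALSE])
              else rep(NA_real_, N)
  data.frame(
    neuron_id = neuronIds(dff), session = session, window = window,
    n_trials = ntr, p_value = pAll,
    responsive = !insufficient & pAll < alpha,
    p_value_odd = pOdd,
    odd_mean = oddMean, even_mean = evenMean, all_mean = rowMeans(resp),
    selected = !insufficient & pOdd < alpha & oddMean > 0,
    insufficient = insufficient,
    stringsAsFactors = FALSE, row.names = NULL)
}

## the stimulus windows tested in each session:
## sound: looming / non-looming onsets and offsets; whisker and pairing:
## stimulus onset; interleaved: matched stimulus onset and the *scheduled*
## onset on mismatch trials.
.sessionWindowDefs <- function(session, d) {
  mk <- function(window, rows, event) list(window = window, rows = rows, event = event)
  defs <- switch(session,
    sound = list(
      mk("looming", which(d$trial_type == "sound_looming"), "sound_onset"),
      mk("nonlooming", which(d$trial_type == "sound_nonlooming"), "sound_onset"),
      mk("looming_offset", which(d$trial_type == "sound_looming"), "sound_offset"),
      mk("nonlooming_offset", which(d$trial_type == "sound_nonlooming"), "sound_offset")),
    whisker = list(mk("whisker", which(d$trial_type == "whisker_only"), "stim_onset")),
    pairing = list(mk("pairing", which(d$trial_type == "paired"), "stim_onset")),
    interleaved = list(
      mk("matched", which(d$trial_type == "matched"), "stim_onset"),
      mk("mismatch", grep("^mismatch_", d$trial_type), "stim_onset")))
  Filter(function(x) length(x$rows) > 0, defs)
}

#' Classify a whole recording across sessions and stimulus windows
#'
#' Runs the shuffle-null classification for every session present in the
#' trial table and every stimulus window defined for it (sound session:
#' looming/non-looming onset and offset; whisker and pairing sessions:
#' stimulus onset; interleaved session: matched onset and the scheduled
#' onset of mismatch trials). One null distribution is built per neuron per
#' session and shared across that session's windows.
#'
#' @param rec a \linkS4class{CalciumRecording}.
#' @param trials the \linkS4class{TrialTable}.
#' @param alpha significance level.
#' @param nDraws null draws per neuron.
#' @param responseLen,baselineLen window lengths in seconds.
#' @param seed RNG seed for null placement.
#' @param pre,post session snippet extent around the cue, seconds.
#' @return data.frame of classification records (rows = neuron x window).
#' @export
classifyRecording <- function(rec, trials, alpha = 0.05, nDraws = 1000,
                              responseLen = 1, baselineLen = 1,
                              seed = 1L, pre = 2, post = 6) {
  d <- trialData(trials)
  records <- list()
  for (sess in intersect(SESSION_LEVELS, unique(d$session))) {
    st <- sessionTensor(rec, trials, sess, pre = pre, post = post)
    defs <- .sessionWindowDefs(sess, st$trials)
    if (!length(defs)) next
    null <- buildNull(st$dff, nDraws = nDraws, responseLen = responseLen,
                      baselineLen = baselineLen,
                      seed = stageSeed(seed, match(sess, SESSION_LEVELS)))
    for (def in defs) {
      af <- eventFrame(st$dff, st$trials, def$event)[def$rows]
      records[[paste(sess, def$window)]] <- classifySession(
        st$dff, null, trialIdx = def$rows, anchorFrames = af,
        session = sess, window = def$window, alpha = alpha,
        responseLen = responseLen, baselineLen = baselineLen)
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Cross-validated selection of positively modulated neurons
#'
#' Filters classification records to the selected cohort (odd-trial
#' significance and positive odd-trial mean) and reports their even-trial
#' means, the statistics downstream analyses use.
#'
#' @param records data.frame from \code{\link{classifySession}} /
#'   \code{\link{classifyRecording}}.
#' @return the selected rows, with an \code{even_report} column equal to the
#'   even-trial mean.
#' @export
crossvalSelect <- function(records) {
  out <- records[records$selected %in% TRUE, , drop = FALSE]
  out$even_report <- out$even_mean
  rownames(out) <- NULL
  out
}

#' Assign response-category labels per neuron
#'
#' One label per (session, window) pair in which the neuron passed the
#' shuffle test; labels are not mutually exclusive, so a neuron significant
#' on both matched and mismatch windows carries both. By default labels
#' come from the cross-validated \code{selected} cohort (positively
#' modulated); \code{selectedOnly = FALSE} uses the bare two-sided
#' \code{responsive} flag instead.
#'
#' @param records classification records.
#' @param selectedOnly use \code{selected} (default) or \code{responsive}.
#' @return named list of character label vectors, one per neuron appearing
#'   in \code{records} (neurons with no label get an empty set).
#' @export
categorize <- function(records, selectedOnly = TRUE) {
  flag <- if (selectedOnly) records$selected else records$responsive
  ids <- unique(records$neuron_id)
  hits <- records[flag %in% TRUE, , drop = FALSE]
  out <- lapply(stats::setNames(nm = ids), function(id)
    unique(hits$window[hits$neuron_id == id]))
  out
}
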
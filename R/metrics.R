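## Derived metrics: per-trial response probability, baseline-corrected
## population averages, stimulus-window and pre-stimulus statistics,
## category overlaps and ground-truth recovery.

## neurons argument resolution: ids, logical mask or indices -> indices
.resolveNeurons <- function(tensor, neurons) {
  if (is.null(neurons)) return(seq_len(nNeurons(tensor)))
  if (is.character(neurons)) {
    idx <- match(neurons, neuronIds(tensor))
    if (anyNA(idx)) stopTyped("validationError", "unknown neuron id")
    return(idx)
  }
  if (is.logical(neurons)) return(which(neurons))
  as.integer(neurons)
}

#' Per-trial response probability
#'
#' A neuron counts as responsive in a trial when its (Savitzky-Golay
#' smoothed) dF/F in the 1 s window from stimulus onset is significantly
#' larger than the 1 s baseline window before it: two-sided rank-sum over
#' the 30-vs-30 frames with p < alpha, *and* post-window median above the
#' pre-window median (the direction a two-sided p cannot encode). The
#' probability is the responsive fraction over all requested trials (odd
#' and even).
#'
#' @param dff a \linkS4class{DffTensor}.
#' @param trialIdx trials of the stimulus condition.
#' @param anchorFrames per-trial response-onset snippet frames (recycled).
#' @param neurons neurons to evaluate (ids, mask or indices; default all).
#' @param alpha per-trial significance level.
#' @param windowLen compared window length, seconds (1 s = 30 frames at 30 Hz).
#' @param smooth smooth single-trial traces first (default TRUE).
#' @param smoothWindowSec SG window, seconds.
#' @return data.frame per neuron: \code{n_responsive_trials},
#'   \code{n_trials}, \code{probability}.
#' @export
responseProbability <- function(dff, trialIdx = seq_len(nTrials(dff)),
                                anchorFrames = anchorFrame(dff),
                                neurons = NULL, alpha = 0.05, windowLen = 1,
                                smooth = TRUE, smoothWindowSec = 0.150) {
  rate <- frameRate(dff)
  nW <- secondsToFrames(windowLen, rate)
  nIdx <- .resolveNeurons(dff, neurons)
  anchorFrames <- rep_len(anchorFrames, length(trialIdx))
  if (any(anchorFrames - nW < 1L) || any(anchorFrames + nW - 1L > nFrames(dff)))
    stopTyped("validationError", sprintf(
      "need %d frames on each side of the stimulus onset", nW))
  v <- tensorValues(dff)[nIdx, trialIdx, , drop = FALSE]
  N <- dim(v)[1]; ntr <- dim(v)[2]; f <- dim(v)[3]
  m <- matrix(aperm(v, c(3, 1, 2)), nrow = f)  # frames x (neuron*trial)
  if (smooth)
    m <- .sgSmoothMatrix(m, n = .sgWindowFrames(smoothWindowSec, rate, 1), p = 1)
  post <- matrix(NA_real_, N * ntr, nW)
  pre <- matrix(NA_real_, N * ntr, nW)
  for (j in seq_len(ntr)) {
    a <- anchorFrames[j]
    cols <- (j - 1L) * N + seq_len(N)
    rows <- (j - 1L) * N + seq_len(N)   # same layout for output
    post[rows, ] <- t(m[a:(a + nW - 1L), cols, drop = FALSE])
    pre[rows, ] <- t(m[(a - nW):(a - 1L), cols, drop = FALSE])
  }
  p <- rankSumPMatrix(post, pre)
  dirUp <- apply(post, 1, stats::median) > apply(pre, 1, stats::median)
  hit <- matrix(p < alpha & dirUp, nrow = N)  # neurons x trials
  data.frame(neuron_id = neuronIds(dff)[nIdx],
             n_responsive_trials = rowSums(hit),
             n_trials = ntr,
             probability = rowMeans(hit),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-neuron mean traces over a trial set
#'
#' @param dff a \linkS4class{DffTensor}.
#' @param neurons neurons (ids, mask or indices; default all).
#' @param trialIdx trials to average (typically the even trials of a
#'   condition).
#' @return numeric matrix, neurons x frames.
#' @export
neuronMeanTraces <- function(dff, neurons = NULL, trialIdx = seq_len(nTrials(dff))) {
  nIdx <- .resolveNeurons(dff, neurons)
  v <- tensorValues(dff)[nIdx, trialIdx, , drop = FALSE]
  out <- apply(v, c(1, 3), mean)
  rownames(out) <- neuronIds(dff)[nIdx]
  out
}

#' Baseline-corrected population average trace
#'
#' Averages the per-neuron mean traces (conventionally even trials of
#' cross-validation-selected neurons) across neurons, then subtracts the
#' mean of the baseline window from the entire averaged trace, so the
#' corrected trace averages exactly zero over the baseline. SEM is across
#' neurons.
#'
#' @param dff a \linkS4class{DffTensor}.
#' @param neurons neuron set (ids, mask or indices).
#' @param trialIdx trial set.
#' @param baselineFrames snippet frame indices of the baseline window used
#'   for correction (1 s before stimulus onset; for delayed stimuli, the
#'   sound presentation window).
#' @return list with \code{mean_trace}, \code{sem_trace}, \code{n_neurons},
#'   \code{time_s}, \code{baseline_frames}, and \code{empty = TRUE} when the
#'   neuron set is empty.
#' @export
populationAverage <- function(dff, neurons, trialIdx = seq_len(nTrials(dff)),
                              baselineFrames) {
  nIdx <- .resolveNeurons(dff, neurons)
  f <- nFrames(dff)
  tS <- (seq_len(f) - anchorFrame(dff)) / frameRate(dff)
  if (!length(nIdx))
    return(list(empty = TRUE, mean_trace = rep(NA_real_, f),
                sem_trace = rep(NA_real_, f), n_neurons = 0L, time_s = tS,
                baseline_frames = baselineFrames))
  M <- neuronMeanTraces(dff, nIdx, trialIdx)
  grand <- colMeans(M)
  corrected <- grand - mean(grand[baselineFrames])
  sem <- if (nrow(M) > 1) apply(M, 2, stats::sd) / sqrt(nrow(M)) else rep(0, f)
  list(empty = FALSE, mean_trace = corrected, sem_trace = sem,
       n_neurons = nrow(M), time_s = tS, baseline_frames = baselineFrames)
}

#' Mean stimulus response from per-neuron average traces
#'
#' Traces whose minimum is negative are first raised so their minimum sits
#' at zero (\code{mode = "shift"}, the default) or excluded
#' (\code{mode = "exclude"}); the response is then the mean over
#' \code{[anchor, anchor + responseLen)} minus the mean over
#' \code{[anchor - baselineLen, anchor)}. The baseline difference makes the
#' value invariant to any constant offset, so the raise only matters for
#' excluded traces.
#'
#' @param traces matrix of per-neuron average traces (neurons x frames),
#'   e.g. from \code{\link{neuronMeanTraces}}.
#' @param anchorFrame 1-based frame where the response window starts.
#' @param frameRate Hz.
#' @param responseLen,baselineLen window lengths, seconds.
#' @param mode "shift" or "exclude".
#' @return numeric vector, one response value per neuron (NA for excluded).
#' @export
meanStimulusResponse <- function(traces, anchorFrame, frameRate,
                                 responseLen = 1, baselineLen = 1,
                                 mode = c("shift", "exclude")) {
  mode <- match.arg(mode)
  nResp <- secondsToFrames(responseLen, frameRate)
  nBase <- secondsToFrames(baselineLen, frameRate)
  mins <- apply(traces, 1, min)
  if (mode == "shift") {
    traces <- traces - pmin(mins, 0)  # raise negative-minimum traces to zero
  }
  post <- rowMeans(traces[, anchorFrame:(anchorFrame + nResp - 1L), drop = FALSE])
  pre <- rowMeans(traces[, (anchorFrame - nBase):(anchorFrame - 1L), drop = FALSE])
  out <- post - pre
  if (mode == "exclude") out[mins < 0] <- NA_real_
  out
}

#' Pre-stimulus (expectation) response per neuron
#'
#' Mean dF/F in the window \code{[stim_onset - prestimLen, stim_onset)} of
#' the per-neuron average trace, corrected by the mean over the baseline
#' window (the sound presentation window when a predictive sound is
#' present).
#'
#' @param dff a \linkS4class{DffTensor}.
#' @param neurons neuron set.
#' @param trialIdx trial set (typically even trials of a condition).
#' @param stimFrame snippet frame of the (scheduled) stimulus onset.
#' @param baselineFrames snippet frames of the correction baseline.
#' @param prestimLen window length in seconds (default 0.5).
#' @return named numeric vector, one value per neuron.
#' @export
prestimulusResponse <- function(dff, neurons, trialIdx, stimFrame,
                                baselineFrames, prestimLen = 0.5) {
  nPre <- secondsToFrames(prestimLen, frameRate(dff))
  if (stimFrame - nPre < 1L)
    stopTyped("validationError", "pre-stimulus window outside the snippet")
  M <- neuronMeanTraces(dff, neurons, trialIdx)
  rowMeans(M[, (stimFrame - nPre):(stimFrame - 1L), drop = FALSE]) -
    rowMeans(M[, baselineFrames, drop = FALSE])
}

#' Category sizes and overlap counts
#'
#' @param assignments named list of per-neuron label sets (from
#'   \code{\link{categorize}} or \code{\link{truthCategories}}).
#' @param categories categories to tabulate; default every label present.
#' @return list with \code{sizes} (named counts), \code{pairs} (named
#'   pairwise intersection counts, names like "a&b") and \code{triples}.
#' @export
overlapCounts <- function(assignments, categories = NULL) {
  if (is.null(categories))
    categories <- sort(unique(unlist(assignments)))
  member <- vapply(categories, function(cat)
    vapply(assignments, function(s) cat %in% s, logical(1)),
    logical(length(assignments)))
  member <- matrix(member, ncol = length(categories),
                   dimnames = list(names(assignments), categories))
  sizes <- colSums(member)
  pairs <- list()
  triples <- list()
  if (length(categories) >= 2) {
    cmb <- utils::combn(categories, 2, simplify = FALSE)
    for (p in cmb)
      pairs[[paste(p, collapse = "&")]] <- sum(member[, p[1]] & member[, p[2]])
  }
  if (length(categories) >= 3) {
    cmb <- utils::combn(categories, 3, simplify = FALSE)
    for (p in cmb)
      triples[[paste(p, collapse = "&")]] <-
        sum(member[, p[1]] & member[, p[2]] & member[, p[3]])
  }
  list(sizes = sizes, pairs = unlist(pairs), triples = unlist(triples))
}

## detected window label corresponding to each planted category
.truthLabelMap <- c(whisker = "whisker", pairing = "pairing",
                    matched = "matched", mismatch = "mismatch",
                    sound = "looming", sound_offset = "looming_offset",
                    ramp = "matched")

#' Recovery of planted categories by the classification
#'
#' Compares detected label sets with simulator ground truth per planted
#' category (planted sound / sound-offset responders map to the looming /
#' looming-offset windows; ramp neurons are matched responders).
#'
#' @param assignments detected label sets from \code{\link{categorize}}.
#' @param truth ground-truth data.frame.
#' @return data.frame per category: \code{n_true}, \code{n_detected},
#'   \code{n_both} and the Jaccard index.
#' @export
categoryRecovery <- function(assignments, truth) {
  tc <- truthCategories(truth)
  cats <- setdiff(sort(unique(unlist(tc))), "ramp")
  rows <- lapply(cats, function(cat) {
    label <- .truthLabelMap[[cat]]
    trueSet <- names(tc)[vapply(tc, function(s)
      any(.truthLabelMap[intersect(s, names(.truthLabelMap))] == label), logical(1))]
    detSet <- names(assignments)[vapply(assignments, function(s)
      label %in% s, logical(1))]
    both <- length(intersect(trueSet, detSet))
    uni <- length(union(trueSet, detSet))
    data.frame(category = cat, label = label, n_true = length(trueSet),
               n_detected = length(detSet), n_both = both,
               jaccard = if (uni) both / uni else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
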
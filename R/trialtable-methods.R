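#' @describeIn TrialTable the underlying data.frame (one row per trial)
#' @param x a TrialTable.
#' @export
setMethod("trialData", "TrialTable", function(x) x@data)

#' @describeIn TrialTable trial ids
#' @export
setMethod("trialIds", "TrialTable", function(x) x@data$trial_id)

#' @describeIn TrialTable number of trials
#' @export
setMethod("nTrials", "TrialTable", function(x) nrow(x@data))

setMethod("show", "TrialTable", function(object) {
  d <- object@data
  counts <- table(factor(d$session, levels = SESSION_LEVELS))
  cat(sprintf("TrialTable: %d trials (%s)\n", nrow(d),
              paste(sprintf("%s %d", names(counts), counts), collapse = ", ")))
})

#' Subset a trial table to one session
#'
#' @param trials a \linkS4class{TrialTable}.
#' @param session one of "sound", "whisker", "pairing", "interleaved".
#' @param trialType optional trial type filter (one or more of
#'   \code{TRIAL_TYPE_LEVELS}).
#' @return data.frame of matching trials.
#' @export
sessionTrials <- function(trials, session, trialType = NULL) {
  d <- trialData(trials)
  keep <- d$session == session
  if (!is.null(trialType)) keep <- keep & d$trial_type %in% trialType
  d[keep, , drop = FALSE]
}
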
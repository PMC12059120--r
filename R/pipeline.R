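## End-to-end orchestration: simulate (or load) -> per-session dF/F ->
## shuffle-null classification -> cross-validated selection -> derived
## metrics -> report bundle.

#' Assemble a pipeline configuration
#'
#' Every analysis parameter carries its protocol default; the configuration
#' (minus the simulator object) is serialized alongside outputs.
#'
#' @param sim a \linkS4class{SimConfig} to simulate from, or NULL to load
#'   recorded inputs.
#' @param tracesPath,trialsPath input files when \code{sim} is NULL.
#' @param alpha significance level for every test.
#' @param nDraws shuffle-null draws per neuron.
#' @param responseLen,baselineLen,prestimLen window lengths, seconds.
#' @param sgWindowSec Savitzky-Golay window for per-trial smoothing, seconds.
#' @param conditionLabel label for the block/condition (e.g. "control").
#' @param seed master seed; stages run on derived substreams.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(sim = simConfig(), tracesPath = NULL,
                           trialsPath = NULL, alpha = 0.05, nDraws = 1000,
                           responseLen = 1, baselineLen = 1, prestimLen = 0.5,
                           sgWindowSec = 0.150, conditionLabel = "control",
                           seed = 1L) {
  structure(list(sim = sim, tracesPath = tracesPath, trialsPath = trialsPath,
                 alpha = alpha, nDraws = nDraws, responseLen = responseLen,
                 baselineLen = baselineLen, prestimLen = prestimLen,
                 sgWindowSec = sgWindowSec, conditionLabel = conditionLabel,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Simulator fields appear under a \code{sim:} mapping with the
#' \code{\link{simConfig}} argument names.
#'
#' @param path YAML file.
#' @return a "PipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) {
    args <- y$sim
    for (nm in c("sessionSizes", "categoryFractions", "categoryAmpScale"))
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    do.call(simConfig, args)
  } else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(pipelineConfig, c(list(sim = sim), args))
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config a "PipelineConfig".
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$sim)) {
    s <- y$sim
    y$sim <- list(nNeurons = s@nNeurons, frameRate = s@frameRate,
                  sessionSizes = as.list(s@sessionSizes),
                  mismatchMode = s@mismatchMode, delay = s@delay,
                  itiRange = s@itiRange, trialLenRange = s@trialLenRange,
                  kernelRise = s@kernelRise, kernelDecay = s@kernelDecay,
                  categoryFractions = as.list(s@categoryFractions),
                  nOverlapMatchedMismatch = s@nOverlapMatchedMismatch,
                  amplitudeMeanlog = s@amplitudeMeanlog,
                  amplitudeSdlog = s@amplitudeSdlog,
                  categoryAmpScale = as.list(s@categoryAmpScale),
                  reliability = s@reliability, noiseSd = s@noiseSd,
                  driftAmplitude = s@driftAmplitude,
                  driftPeriod = s@driftPeriod, baselineF = s@baselineF,
                  prestimRampAmp = s@prestimRampAmp, seed = s@seed)
  }
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

## window geometry of one analysis window within a session tensor: trial
## rows, response-onset frames and the baseline-correction frames (the sound
## presentation window when a predictive sound precedes the stimulus,
## otherwise the 1 s before the response window).
.windowGeometry <- function(st, def, baselineLen = 1) {
  dff <- st$dff; d <- st$trials
  af <- eventFrame(dff, d, def$event)[def$rows]
  nBase <- secondsToFrames(baselineLen, frameRate(dff))
  hasSound <- !anyNA(d$sound_onset_s[def$rows])
  base <- if (def$event == "stim_onset" && hasSound) {
    s0 <- eventFrame(dff, d, "sound_onset")[def$rows][1]
    s1 <- eventFrame(dff, d, "sound_offset")[def$rows][1]
    s0:(s1 - 1L)
  } else {
    (af[1] - nBase):(af[1] - 1L)
  }
  list(rows = def$rows, anchorFrames = af, baselineFrames = base,
       stimFrame = af[1])
}

.oddIdx <- function(n) seq(1L, n, by = 2L)
.evenIdx <- function(n) if (n >= 2L) seq(2L, n, by = 2L) else integer(0)

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a recording, classifies every neuron against its
#' per-session shuffle null, applies odd/even cross-validated selection,
#' and computes the derived metrics: per-category counts and response
#' probabilities, baseline-corrected population averages and mean stimulus
#' responses on even trials, matched-vs-mismatch comparison, pre-stimulus
#' expectation statistics (pairing vs interleaved), category overlaps, and
#' -- on synthetic input -- recovery against ground truth. Deterministic
#' given \code{seed}.
#'
#' @param config a "PipelineConfig" from \code{\link{pipelineConfig}}.
#' @param outDir optional output directory; when given, writes
#'   classification.csv, metrics.json, population_averages.csv,
#'   overlaps.json, report.json, config.yaml and (synthetic runs)
#'   ground_truth.json.
#' @param seed master seed override (default: the config's).
#' @param quiet suppress stage messages.
#' @return the report bundle (named list), invisibly containing the full
#'   classification records as attribute "records".
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        seed = config$seed, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  ## stage: inputs
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulateExperiment(config$sim, seed = seed)
    rec <- sim$recording; trials <- sim$trials; truth <- sim$truth
    say("simulated %d neurons, %d trials", nNeurons(rec), nTrials(trials))
  } else {
    if (is.null(config$tracesPath) || is.null(config$trialsPath))
      stopTyped("configError", "need tracesPath and trialsPath when sim is NULL")
    rec <- loadRecording(config$tracesPath)
    trials <- loadTrialTable(config$trialsPath)
    say("loaded %d neurons, %d trials", nNeurons(rec), nTrials(trials))
  }
  tick("inputs")

  ## stage: classification (per-session tensors + shuffle nulls)
  records <- classifyRecording(rec, trials, alpha = config$alpha,
                               nDraws = config$nDraws,
                               responseLen = config$responseLen,
                               baselineLen = config$baselineLen,
                               seed = stageSeed(seed, "null"))
  categories <- categorize(records)
  say("classified %d neuron x window records, %d labelled neurons",
      nrow(records), sum(lengths(categories) > 0))
  tick("classification")

  ## stage: metrics
  d <- trialData(trials)
  nTotal <- nNeurons(rec)
  windows <- unique(records$window)
  counts <- vapply(windows, function(w)
    sum(records$selected[records$window == w] %in% TRUE), integer(1))
  catSummary <- data.frame(window = windows, n_selected = as.integer(counts),
                           fraction = as.numeric(counts) / nTotal,
                           stringsAsFactors = FALSE)

  popRows <- list(); respProb <- list(); meanResp <- list(); prestim <- list()
  for (sess in intersect(SESSION_LEVELS, unique(d$session))) {
    st <- sessionTensor(rec, trials, sess)
    for (def in .sessionWindowDefs(sess, st$trials)) {
      geo <- .windowGeometry(st, def, config$baselineLen)
      sel <- records$neuron_id[records$window == def$window &
                               records$selected %in% TRUE]
      ntr <- length(geo$rows)
      evenRows <- geo$rows[.evenIdx(ntr)]
      if (length(sel)) {
        rp <- responseProbability(st$dff, trialIdx = geo$rows,
                                  anchorFrames = geo$anchorFrames,
                                  neurons = sel, alpha = config$alpha,
                                  smoothWindowSec = config$sgWindowSec)
        respProb[[def$window]] <- mean(rp$probability)
        pa <- populationAverage(st$dff, sel, evenRows, geo$baselineFrames)
        popRows[[def$window]] <- data.frame(
          condition = def$window, time_s = pa$time_s, mean = pa$mean_trace,
          sem = pa$sem_trace, n = pa$n_neurons, stringsAsFactors = FALSE)
        traces <- neuronMeanTraces(st$dff, sel, evenRows)
        mr <- meanStimulusResponse(traces, geo$stimFrame, frameRate(st$dff),
                                   config$responseLen, config$baselineLen)
        meanResp[[def$window]] <- mr
      }
      ## pre-stimulus expectation window on even trials, every neuron
      if (def$event == "stim_onset" && !anyNA(st$trials$sound_onset_s[geo$rows]))
        prestim[[def$window]] <- prestimulusResponse(
          st$dff, NULL, evenRows, geo$stimFrame, geo$baselineFrames,
          config$prestimLen)
    }
  }

  ## matched vs mismatch comparison on even-trial mean responses
  mmCompare <- if (!is.null(meanResp$matched) && !is.null(meanResp$mismatch))
    compareGroups(meanResp$mismatch, meanResp$matched, paired = FALSE)
  else NULL

  ## expectation correlate: pre-stimulus response of the interleaved
  ## matched-selected cohort, pairing session vs interleaved matched trials
  prestimStats <- NULL
  if (!is.null(prestim$pairing) && !is.null(prestim$matched)) {
    sel <- records$neuron_id[records$window == "matched" &
                             records$selected %in% TRUE]
    common <- intersect(sel, intersect(names(prestim$pairing),
                                       names(prestim$matched)))
    dropped <- setdiff(sel, common)
    if (length(dropped))
      say("pre-stimulus paired test: dropped %d neurons absent in a session",
          length(dropped))
    if (length(common) >= 5) {
      cmp <- compareGroups(prestim$matched[common], prestim$pairing[common],
                           paired = TRUE)
      prestimStats <- c(cmp, list(
        mean_pairing = mean(prestim$pairing[common]),
        mean_interleaved = mean(prestim$matched[common]),
        n_dropped = length(dropped)))
    }
  }

  overlaps <- overlapCounts(categories)
  recovery <- if (!is.null(truth)) categoryRecovery(categories, truth) else NULL

  ## calibration section when the cohort contains no planted responder
  calibration <- NULL
  allNull <- !is.null(truth) && all(truth$categories == "none")
  if (allNull || is.null(truth)) {
    tested <- records[!records$insufficient, , drop = FALSE]
    calibration <- list(
      all_null_cohort = allNull,
      n_tests = nrow(tested),
      fraction_responsive = mean(tested$responsive),
      fraction_selected = mean(tested$selected))
    if (allNull) say("all-null cohort: calibration section emitted")
  }
  tick("metrics")

  report <- list(
    schema_version = "1.0",
    condition = config$conditionLabel,
    seed = as.integer(seed),
    n_neurons = nTotal,
    n_trials = nTrials(trials),
    category_summary = catSummary,
    response_probability = respProb,
    mean_stimulus_response = lapply(meanResp, function(x)
      list(mean = mean(x), median = stats::median(x), n = length(x))),
    matched_mismatch_comparison = mmCompare,
    prestimulus = prestimStats,
    overlaps = overlaps,
    recovery = recovery,
    calibration = calibration,
    timings = timings)
  .checkReport(report)

  if (!is.null(outDir)) {
    writeResults(records, outDir, metrics = report[setdiff(names(report),
                                                           "category_summary")])
    if (length(popRows))
      utils::write.csv(do.call(rbind, popRows),
                       file.path(outDir, "population_averages.csv"),
                       row.names = FALSE)
    jsonlite::write_json(overlaps, file.path(outDir, "overlaps.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", dataframe = "rows")
    writePipelineConfig(config, file.path(outDir, "config.yaml"))
    if (!is.null(truth))
      writeGroundTruth(truth, file.path(outDir, "ground_truth.json"))
    say("wrote outputs to %s", outDir)
  }
  tick("report")
  report$timings <- timings
  attr(report, "records") <- records
  invisible(report)
}

## minimal schema check before any write
.checkReport <- function(report) {
  need <- c("schema_version", "condition", "seed", "n_neurons", "n_trials",
            "category_summary", "overlaps", "timings")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stopTyped("validationError", "report schema violation, missing: ",
              paste(missing, collapse = ", "))
  invisible(TRUE)
}
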
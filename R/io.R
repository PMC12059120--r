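## On-disk formats.
##
## Traces: CSV, wide matrix with header = neuron ids (one row per frame),
## preceded by metadata comment lines "# frame_rate_hz: 30" and
## "# block_id: control". Trial table: plain CSV with the canonical columns.
## Results: classification.csv + metrics.json; ground truth: JSON.

#' Write a CalciumRecording to a traces CSV file
#'
#' @param rec a \linkS4class{CalciumRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate_hz: %.10g", frameRate(rec)),
               sprintf("# block_id: %s", blockId(rec))), con)
  d <- as.data.frame(t(fluorescence(rec)))
  names(d) <- neuronIds(rec)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Load a CalciumRecording from a traces CSV file
#'
#' The file must carry a \code{# frame_rate_hz:} metadata line; traces with
#' NaN/Inf entries are rejected with the offending neuron and frame named.
#'
#' @param path traces CSV file.
#' @return a \linkS4class{CalciumRecording}.
#' @export
loadRecording <- function(path) {
  if (!file.exists(path)) stopTyped("ioError", "no such file: ", path)
  head <- readLines(path, n = 50L)
  meta <- grep("^#", head, value = TRUE)
  getMeta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", ln[1]))
  }
  fr <- getMeta("frame_rate_hz")
  if (is.null(fr) || is.na(suppressWarnings(as.numeric(fr))))
    stopTyped("formatError", "traces file lacks a frame_rate_hz attribute: ", path)
  block <- getMeta("block_id") %||% "block1"
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- t(as.matrix(d))
  if (!is.numeric(m)) stopTyped("formatError", "non-numeric trace values in ", path)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stopTyped("validationError", sprintf(
      "non-finite fluorescence at neuron '%s', frame %d", rownames(m)[bad[1]], bad[2]))
  }
  CalciumRecording(m, frameRate = as.numeric(fr), neuronIds = rownames(m),
                   blockId = block)
}

#' Write a TrialTable to CSV
#'
#' @param trials a \linkS4class{TrialTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.csv(trialData(trials)[, TRIAL_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Load and validate a trial table CSV
#'
#' Enum fields are parsed strictly; any invariant violation (unknown labels,
#' non-monotone times, omission trials with nonzero intensity, ...) raises a
#' validation error.
#'
#' @param path trial table CSV with columns \code{trial_id, session,
#'   trial_type, cue_onset_s, sound_onset_s, sound_offset_s, stim_onset_s,
#'   intensity_pct, delay_s}.
#' @return a \linkS4class{TrialTable}.
#' @export
loadTrialTable <- function(path) {
  if (!file.exists(path)) stopTyped("ioError", "no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(session = "character",
                                      trial_type = "character"))
  TrialTable(d)
}

#' Write classification records and metric tables
#'
#' Writes \code{classification.csv} (one row per neuron x session x window)
#' and, when given, \code{metrics.json} with population summaries.
#'
#' @param records data.frame of classification records
#'   (see \code{\link{classifySession}}).
#' @param dir output directory (created if needed).
#' @param metrics optional named list written as \code{metrics.json}.
#' @return character vector of files written, invisibly.
#' @export
writeResults <- function(records, dir, metrics = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stopTyped("ioError", "cannot create directory: ", dir)
  files <- file.path(dir, "classification.csv")
  utils::write.csv(records, files, row.names = FALSE, na = "")
  if (!is.null(metrics)) {
    mpath <- file.path(dir, "metrics.json")
    jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    files <- c(files, mpath)
  }
  invisible(files)
}

#' Read back classification records written by \code{writeResults}
#'
#' @param dir directory containing \code{classification.csv}.
#' @return data.frame of classification records with typed columns.
#' @export
readResults <- function(dir) {
  path <- file.path(dir, "classification.csv")
  if (!file.exists(path)) stopTyped("ioError", "no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("responsive", "selected", "insufficient"), names(d)))
    d[[cl]] <- as.logical(d[[cl]])
  d
}

#' Write simulator ground truth to JSON
#'
#' @param truth ground-truth data.frame from \code{\link{assignGroundTruth}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  out <- lapply(seq_len(nrow(truth)), function(i) list(
    neuron_id = truth$neuron_id[i],
    categories = as.list(truthCategories(truth)[[i]]),
    true_amplitude = truth$true_amplitude[i],
    true_reliability = truth$true_reliability[i]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulator ground truth from JSON
#'
#' @param path JSON file written by \code{\link{writeGroundTruth}}.
#' @return ground-truth data.frame.
#' @export
readGroundTruth <- function(path) {
  raw <- jsonlite::read_json(path)
  data.frame(
    neuron_id = vapply(raw, function(x) x$neuron_id, character(1)),
    categories = vapply(raw, function(x) {
      s <- paste(unlist(x$categories), collapse = ",")
      if (nzchar(s)) s else "none"
    }, character(1)),
    true_amplitude = vapply(raw, function(x) as.numeric(x$true_amplitude), numeric(1)),
    true_reliability = vapply(raw, function(x) as.numeric(x$true_reliability), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Per-neuron category sets from a ground-truth table
#'
#' @param truth ground-truth data.frame.
#' @return named list of character vectors, one per neuron ("none" becomes
#'   an empty set).
#' @export
truthCategories <- function(truth) {
  out <- lapply(strsplit(truth$categories, ",", fixed = TRUE), function(x) {
    x <- x[nzchar(x) & x != "none"]
    x
  })
  names(out) <- truth$neuron_id
  out
}
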
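# Plain-text containers: CSV for tables and signal matrices, JSON
# sidecars for metadata. Kept deliberately simple so every artefact of a
# run is diffable and portable.

#' Write / read a behavioural trial table
#'
#' Column layout: participant, block, trial, stimulus_class (+1 target /
#' -1 non-target), decision (+1/-1), correct (0/1), rt (seconds),
#' reported_confidence (0-100 in steps of 10, may be NA),
#' second_decision (+1/-1 or NA).
#'
#' @param trials Data frame as produced by \code{\link{simulate_session}}.
#' @param path Output CSV path.
#' @return \code{write_trials_csv}: the path, invisibly;
#'   \code{read_trials_csv}: the data frame.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- read.csv(path)
  tr$correct <- as.logical(tr$correct)
  tr
}

#' Write a continuous recording to a CSV + JSON sidecar container
#'
#' The signal matrix goes to \code{<path>.csv} (samples in rows, one
#' column per channel); the sampling rate, channel labels and event
#' markers go to \code{<path>.json}. Intended for small recordings and
#' fixtures; full-rate sessions are better regenerated from their
#' configuration seed.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Path stem (without extension).
#' @return \code{write_recording}: the path stem, invisibly;
#'   \code{read_recording}: the recording.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- as.data.frame(t(rec$signal))
  names(sig) <- rec$channels
  write.csv(sig, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channels, reference = rec$reference,
         events = rec$events),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(read.csv(paste0(path, ".csv"), check.names = FALSE))
  rec <- eeg_recording(t(sig), meta$channels, meta$fs,
                       as.data.frame(meta$events))
  rec$reference <- meta$reference
  if (!identical(meta$reference, "raw"))
    attr(rec, "ref_channels") <- earlobe_channels()
  rec
}

#' Serialise a fitted confidence model to JSON
#'
#' Stores the coefficients, intercept, selected regularisation strength,
#' training standardisation parameters and the label convention, so the
#' model can be re-applied without refitting.
#'
#' @param model A \code{\link{fit_confidence_model}} result.
#' @param path Output JSON path.
#' @return \code{write_confidence_model}: the path, invisibly;
#'   \code{read_confidence_model}: the model.
#' @export
write_confidence_model <- function(model, path) {
  stopifnot(inherits(model, "confidence_model"))
  jsonlite::write_json(
    list(coef = model$coef, intercept = model$intercept, C = model$C,
         mu = model$mu, sigma = model$sigma,
         labels = as.list(model$labels),
         cv_fallback = model$cv_fallback),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_confidence_model
#' @export
read_confidence_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coef = as.numeric(x$coef), intercept = x$intercept, C = x$C,
         mu = as.numeric(x$mu), sigma = as.numeric(x$sigma),
         labels = unlist(x$labels), cv = NULL,
         inner_fold_sizes = integer(), cv_fallback = isTRUE(x$cv_fallback)),
    class = "confidence_model")
}

#' Write per-group error rates and a run manifest
#'
#' @param result An \code{hbci_cv_result} from
#'   \code{\link{run_pipeline_cv}}.
#' @param path Path stem: errors go to \code{<path>.csv}, the manifest
#'   (seed, methods, participant count) to \code{<path>_manifest.json}.
#' @return The path stem, invisibly.
#' @export
write_cv_result <- function(result, path) {
  stopifnot(inherits(result, "hbci_cv_result"))
  write.csv(result$errors, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$seed, methods = result$methods,
         n_participants = nrow(result$individual),
         n_trials = nrow(result$trials),
         individual_error = result$individual$error_rate),
    paste0(path, "_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
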
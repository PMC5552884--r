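#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous recording: a channels-by-samples
#' signal matrix in microvolts, channel labels, the sampling rate and a
#' table of event markers (one \code{stimulus_onset} and at most one
#' \code{response} per trial).
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param channels Character vector of channel labels, one per row.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with columns \code{kind}
#'   (\code{"stimulus_onset"} or \code{"response"}), \code{sample}
#'   (1-based sample index) and \code{trial} (trial index).
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(signal, channels, fs, events) {
  if (!is.matrix(signal)) stop("signal must be a channels x samples matrix")
  if (length(channels) != nrow(signal))
    stop("one channel label per signal row is required")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  events <- as.data.frame(events)
  need <- c("kind", "sample", "trial")
  if (!all(need %in% names(events)))
    stop("events must have columns kind, sample, trial")
  if (!all(events$kind %in% c("stimulus_onset", "response")))
    stop("event kind must be stimulus_onset or response")
  if (any(events$sample < 1L | events$sample > ncol(signal)))
    stop("event sample indices must lie within the recording")
  per <- table(events$trial, events$kind)
  if (any(per[, "stimulus_onset"] != 1L))
    stop("each trial needs exactly one stimulus_onset marker")
  if ("response" %in% colnames(per) && any(per[, "response"] > 1L))
    stop("each trial may have at most one response marker")
  rownames(signal) <- channels
  structure(
    list(signal = signal, channels = channels, fs = fs,
         events = events, reference = "raw"),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, reference: %s\n",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
    nrow(x$events), x$reference
  ))
  invisible(x)
}

# sample indices of one event kind, ordered by trial
event_samples <- function(rec, kind) {
  ev <- rec$events[rec$events$kind == kind, , drop = FALSE]
  ev <- ev[order(ev$trial), , drop = FALSE]
  stats::setNames(ev$sample, ev$trial)
}
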
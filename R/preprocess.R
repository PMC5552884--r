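#' Re-reference a recording to the average of the earlobe electrodes
#'
#' Subtracts the sample-wise mean of the two earlobe channels from every
#' scalp channel. The earlobe rows are kept (zeroed) so channel indexing
#' is stable, but they are excluded from all downstream analysis; applying
#' the operation twice is therefore a no-op.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param refs Labels of the two earlobe channels.
#' @return The re-referenced recording (\code{reference = "earlobes"}).
#' @export
rereference_earlobes <- function(rec, refs = earlobe_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(refs, rec$channels)
  if (length(miss) > 0)
    stop("earlobe channel(s) missing from the recording: ",
         paste(miss, collapse = ", "))
  ri <- match(refs, rec$channels)
  ref <- colMeans(rec$signal[ri, , drop = FALSE])
  scalp <- setdiff(seq_len(nrow(rec$signal)), ri)
  rec$signal[scalp, ] <- sweep(rec$signal[scalp, , drop = FALSE], 2, ref)
  rec$signal[ri, ] <- 0
  rec$reference <- "earlobes"
  attr(rec, "ref_channels") <- refs
  rec
}

#' Band-pass filter a continuous recording
#'
#' Applies a linear-phase FIR band-pass (default 0.15-40 Hz) to every
#' channel, forward with the group delay compensated so the net delay is
#' zero. The default tap count is 14677 at 2048 Hz and scales
#' proportionally at other rates; the design is DC-nulled so constant
#' offsets are removed exactly.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param low,high Band edges in Hz.
#' @param n_taps Filter length (odd); default \code{round(14677 * fs/2048)}
#'   made odd.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.15, high = 40, n_taps = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  if (is.null(n_taps)) {
    n_taps <- round(14677 * rec$fs / 2048)
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  if (n_taps %% 2L == 0L) stop("n_taps must be odd (even-order FIR)")
  b <- design_bandpass(rec$fs, low, high, n_taps)
  rec$signal <- t(fir_apply(b, t(rec$signal)))
  rownames(rec$signal) <- rec$channels
  rec
}

#' Remove ocular artefacts by regression on a frontal difference proxy
#'
#' Builds the ocular proxy \code{o(t)}, the average of the differences
#' Fp1-F1 and Fp2-F2, and subtracts from every channel its least-squares
#' projection onto the proxy (coefficient \code{cov(channel, o)/var(o)}).
#' After correction every channel's sample correlation with the proxy is
#' approximately zero. A proxy with zero variance leaves the recording
#' unchanged with a warning.
#'
#' @param rec An \code{\link{eeg_recording}} containing channels Fp1, F1,
#'   Fp2 and F2.
#' @return The corrected recording.
#' @export
remove_ocular <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- c("Fp1", "F1", "Fp2", "F2")
  miss <- setdiff(need, rec$channels)
  if (length(miss) > 0)
    stop("ocular-regression channel(s) missing: ",
         paste(miss, collapse = ", "))
  g <- function(ch) rec$signal[match(ch, rec$channels), ]
  o <- ((g("Fp1") - g("F1")) + (g("Fp2") - g("F2"))) / 2
  vo <- var(o)
  if (!is.finite(vo) || vo <= 0) {
    warning("ocular proxy has zero variance; recording returned unchanged")
    return(rec)
  }
  oc <- o - mean(o)
  # beta_ch = cov(ch, o) / var(o), all channels at once
  beta <- (rec$signal %*% oc) / sum(oc^2)
  refs <- attr(rec, "ref_channels")
  if (!is.null(refs)) beta[match(refs, rec$channels)] <- 0
  rec$signal <- rec$signal - beta %*% t(o)
  rownames(rec$signal) <- rec$channels
  rec
}

# epoch geometry shared by extract_epochs and condition_epoch:
# raw epochs hold 48 * (fs/32) retained samples plus a 200 ms trim margin
# on each side (3892 samples at 2048 Hz; 48 + 2*410 margin samples)
epoch_geometry <- function(fs) {
  if (fs %% 32 != 0) stop("sampling rate must be a multiple of 32 Hz")
  factor <- fs %/% 32L
  trim <- round(0.2 * fs)
  list(factor = factor, trim = trim,
       n_keep = 48L * factor, n_raw = 48L * factor + 2L * trim)
}

#' Extract raw stimulus- and response-locked epochs
#'
#' Cuts, for every trial, two windows of nominal 1900 ms from the
#' continuous recording: stimulus-locked \code{[-200, +1700)} ms around
#' stimulus onset and response-locked \code{[-1200, +700)} ms around the
#' response. Windows are half-open in sample indices and include the
#' event sample. Trials whose window would extend past the recording are
#' excluded and reported. Earlobe reference channels (when the recording
#' has been re-referenced) are dropped here.
#'
#' @param rec An \code{\link{eeg_recording}} with event markers.
#' @return A list of class \code{raw_epochs}: \code{stimulus} and
#'   \code{response} arrays (channels x samples x trials), \code{trials}
#'   (included trial indices per lock), \code{excluded} (data frame),
#'   \code{channels}, \code{fs}.
#' @export
extract_epochs <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  geom <- epoch_geometry(rec$fs)
  refs <- attr(rec, "ref_channels")
  keep_ch <- if (is.null(refs)) rec$channels else
    setdiff(rec$channels, refs)
  ci <- match(keep_ch, rec$channels)
  n_samp <- ncol(rec$signal)

  stim <- event_samples(rec, "stimulus_onset")
  resp <- event_samples(rec, "response")
  starts <- list(
    stimulus = stim - geom$trim,
    response = resp - round(1.2 * rec$fs)
  )
  out <- list(channels = keep_ch, fs = rec$fs, geometry = geom)
  excluded <- data.frame(trial = integer(), lock = character(),
                         reason = character())
  for (lock in c("stimulus", "response")) {
    st <- starts[[lock]]
    trial_ids <- as.integer(names(st))
    ok <- st >= 1L & (st + geom$n_raw - 1L) <= n_samp
    if (any(!ok))
      excluded <- rbind(excluded, data.frame(
        trial = trial_ids[!ok], lock = lock,
        reason = "window outside recording"))
    kept <- which(ok)
    arr <- array(NA_real_,
                 dim = c(length(ci), geom$n_raw, length(kept)),
                 dimnames = list(keep_ch, NULL, trial_ids[kept]))
    for (j in seq_along(kept)) {
      s0 <- st[kept[j]]
      arr[, , j] <- rec$signal[ci, s0:(s0 + geom$n_raw - 1L)]
    }
    out[[lock]] <- arr
    out$trials[[lock]] <- trial_ids[kept]
  }
  out$excluded <- excluded
  class(out) <- "raw_epochs"
  out
}

#' Condition a raw epoch to the common 48-sample grid
#'
#' Per channel: linear detrend, equiripple low-pass (pass edge 14 Hz,
#' stop edge 16 Hz, designed with the Remez exchange algorithm, applied
#' with zero net delay), trimming of the 200 ms margins, and decimation
#' to 32 Hz by keeping every \code{fs/32}-th sample. The output always
#' has exactly 48 samples per channel (1.5 s); 64 channels give 3072
#' values.
#'
#' @param epoch Channels x samples matrix at the acquisition rate, with
#'   \code{samples = 48 * fs/32 + 2 * round(0.2 * fs)} (the raw window
#'   cut by \code{\link{extract_epochs}}).
#' @param fs Acquisition sampling rate in Hz (multiple of 32).
#' @param lp_order Optional low-pass filter order (default
#'   \code{min(1200, 0.75 * fs)}).
#' @return Channels x 48 matrix with attributes \code{fs} (32) and
#'   \code{times} (seconds within the trimmed window).
#' @export
condition_epoch <- function(epoch, fs, lp_order = NULL) {
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1)
  geom <- epoch_geometry(fs)
  if (ncol(epoch) != geom$n_raw)
    stop("epoch must have ", geom$n_raw, " samples at ", fs,
         " Hz (got ", ncol(epoch), ")")
  b <- design_lowpass_remez(fs, order = lp_order)
  x <- detrend_linear(t(epoch))
  x <- fir_apply(b, x)
  kept <- geom$trim + seq_len(geom$n_keep)
  dec <- kept[seq(1L, geom$n_keep, by = geom$factor)]
  out <- t(x[dec, , drop = FALSE])
  stopifnot(ncol(out) == 48L)
  rownames(out) <- rownames(epoch)
  attr(out, "fs") <- 32
  attr(out, "times") <- (seq_len(48L) - 1L) / 32
  out
}

#' Preprocess a simulated session end to end
#'
#' Runs the full conditioning chain on one session: earlobe
#' re-referencing, band-pass filtering, ocular-artefact regression,
#' epoch extraction and per-epoch conditioning to the 48-sample grid.
#'
#' @param session An \code{hbci_session} with a recording.
#' @param n_taps Band-pass length passed to \code{\link{bandpass_filter}}.
#' @param lp_order Low-pass order passed to \code{\link{condition_epoch}}.
#' @return A list of class \code{processed_session}: \code{stimulus} and
#'   \code{response} arrays (channels x 48 x trials), \code{trials}
#'   (behavioural table restricted to trials with both epochs),
#'   \code{channels}, \code{excluded}.
#' @export
preprocess_session <- function(session, n_taps = NULL, lp_order = NULL) {
  stopifnot(inherits(session, "hbci_session"))
  if (is.null(session$recording))
    stop("session has no recording (simulated with eeg = FALSE)")
  rec <- rereference_earlobes(session$recording)
  rec <- bandpass_filter(rec, n_taps = n_taps)
  rec <- remove_ocular(rec)
  raw <- extract_epochs(rec)
  keep <- intersect(raw$trials$stimulus, raw$trials$response)
  # all epochs of one lock are conditioned in a single filtering pass
  # (same maths as condition_epoch applied per epoch)
  cond <- function(lock) {
    idx <- match(keep, raw$trials[[lock]])
    arr <- raw[[lock]][, , idx, drop = FALSE]
    geom <- raw$geometry
    n_ch <- dim(arr)[1]; n_ep <- dim(arr)[3]
    x <- matrix(aperm(arr, c(2, 1, 3)), nrow = geom$n_raw)
    x <- detrend_linear(x)
    x <- fir_apply(design_lowpass_remez(raw$fs, order = lp_order), x)
    dec <- geom$trim + seq(1L, geom$n_keep, by = geom$factor)
    out <- aperm(array(x[dec, ], dim = c(48L, n_ch, n_ep)), c(2, 1, 3))
    dimnames(out) <- list(raw$channels, NULL, keep)
    out
  }
  structure(
    list(stimulus = cond("stimulus"), response = cond("response"),
         trials = session$trials[match(keep, session$trials$trial), ],
         channels = raw$channels, excluded = raw$excluded),
    class = "processed_session"
  )
}

#' @export
print.processed_session <- function(x, ...) {
  cat(sprintf(
    "<processed_session> %d trials x %d channels x 48 samples @ 32 Hz (%d excluded)\n",
    dim(x$stimulus)[3], dim(x$stimulus)[1], nrow(x$excluded)))
  invisible(x)
}
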
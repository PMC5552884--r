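# Shared fixtures: all synthetic, generated in code at test time.

# small cohort configuration used by pipeline-level tests (reduced rate
# and montage so the full chain stays fast)
small_config <- function(...) {
  sim_config(n_participants = 4, n_blocks = 2, trials_per_block = 20,
             sampling_rate = 128, n_channels = 8, error_rate = 0.25,
             seed = 11, ...)
}

# the reduced-montage study conditions used for parameter-recovery runs
study_config <- function(seed, ...) {
  sim_config(n_participants = 10, sampling_rate = 128, n_channels = 8,
             seed = seed, ...)
}

# hand-built continuous recording: deterministic content, channel labels
# including the ocular-regression and earlobe sites
toy_recording <- function(n_ch = 8, n_samp = 4096, fs = 128,
                          stim = NULL, resp = NULL, signal = NULL) {
  channels <- c(montage_channels(n_ch), earlobe_channels())
  if (is.null(signal))
    signal <- matrix(rnorm((n_ch + 2) * n_samp), n_ch + 2, n_samp)
  if (is.null(stim)) stim <- round(n_samp / 2)
  ev <- data.frame(kind = "stimulus_onset", sample = stim,
                   trial = seq_along(stim))
  if (!is.null(resp))
    ev <- rbind(ev, data.frame(kind = "response", sample = resp,
                               trial = seq_along(resp)))
  eeg_recording(signal, channels, fs, ev)
}

# single-sided amplitude of frequency f in a signal sampled at fs,
# estimated by least squares on sin/cos regressors (robust to
# non-integer cycle counts)
tone_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  b <- coef(lm(x ~ X))
  sqrt(b[2]^2 + b[3]^2)
}

# rank-based AUC of scores against binary labels
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
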
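#' Configuration for the synthetic-cohort simulator
#'
#' Builds and validates the parameter set of the synthetic experiment the
#' simulator emulates: a rapid visual-search task run in blocks with a
#' fixed target prevalence, correctness-dependent response times and
#' event-related potential (ERP) amplitudes, and optionally a
#' computer-mediated communication condition that attenuates the
#' correct-vs-incorrect ERP difference and decouples reported confidence
#' from correctness.
#'
#' @param n_participants Number of participants in a cohort.
#' @param n_blocks Number of blocks per session (default 8).
#' @param trials_per_block Trials per block (default 40).
#' @param target_fraction Fraction of target trials per block (default
#'   0.25); \code{target_fraction * trials_per_block} must be an integer so
#'   prevalence is exact in every block.
#' @param sampling_rate EEG sampling rate in Hz (default 2048); must be an
#'   integer multiple of 32 so epochs decimate exactly to 32 Hz.
#' @param n_channels Number of scalp channels (default 64); two earlobe
#'   reference channels are always appended.
#' @param error_rate Per-participant probability of an incorrect decision.
#' @param rt_correct,rt_incorrect Log-normal response-time parameters,
#'   lists with \code{location} (median, seconds) and \code{scale}
#'   (standard deviation of log RT). Incorrect decisions are slower on
#'   average by default.
#' @param erp_attenuation_incorrect Multiplicative factor in (0, 1]
#'   applied to the ERP template amplitude on incorrect trials.
#' @param communication_mode Logical; when \code{TRUE} participants are
#'   paired, reported confidence becomes independent of correctness, the
#'   incorrect-trial ERP attenuation is pulled toward 1 (smaller
#'   correct/incorrect difference) and overall ERP amplitude shrinks.
#' @param confidence_noise Standard deviation of reported confidence on
#'   the 0-100 scale before quantisation to 10-point steps.
#' @param confidence_coupling Strength of the correctness effect on
#'   reported confidence when communication is off (scales a +/-15 point
#'   offset).
#' @param conformity Probability that a disagreeing pair converges on a
#'   shared second response (communication mode only).
#' @param noise_sd Background noise standard deviation in microvolts.
#' @param noise_type \code{"white"} (default) or \code{"pink"} (1/f).
#' @param erp_amplitude Peak template amplitude in microvolts.
#' @param erp_channels Channels carrying the template.
#' @param erp_latency,erp_width Latency and width (s) of the
#'   stimulus-locked template peak.
#' @param resp_latency,resp_width Peak position relative to the response
#'   and width (s) of the response-locked template.
#' @param comm_attenuation_scale In communication mode the effective
#'   incorrect-trial attenuation becomes
#'   \code{1 - (1 - erp_attenuation_incorrect) * comm_attenuation_scale}.
#' @param comm_amplitude_scale Overall ERP amplitude factor in
#'   communication mode.
#' @param blink_rate Ocular blink rate (events per minute).
#' @param blink_amplitude Blink amplitude in microvolts at Fp1/Fp2.
#' @param iti Inter-trial interval: seconds of recording per trial
#'   (default 4, so response-locked epochs never overlap neighbours).
#' @param seed Integer seed; identical configurations and seeds produce
#'   bit-identical sessions.
#' @return An object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(n_participants = 2, sampling_rate = 128, n_channels = 8)
#' cfg$n_blocks * cfg$trials_per_block
#' @export
sim_config <- function(n_participants = 10,
                       n_blocks = 8,
                       trials_per_block = 40,
                       target_fraction = 0.25,
                       sampling_rate = 2048,
                       n_channels = 64,
                       error_rate = 0.2,
                       rt_correct = list(location = 0.8, scale = 0.3),
                       rt_incorrect = list(location = 1.1, scale = 0.3),
                       erp_attenuation_incorrect = 0.5,
                       communication_mode = FALSE,
                       confidence_noise = 15,
                       confidence_coupling = 1,
                       conformity = 0.5,
                       noise_sd = 10,
                       noise_type = c("white", "pink"),
                       erp_amplitude = 5,
                       erp_channels = c("Cz", "CPz", "Pz", "POz"),
                       erp_latency = 0.45,
                       erp_width = 0.12,
                       resp_latency = -0.1,
                       resp_width = 0.15,
                       comm_attenuation_scale = 0.4,
                       comm_amplitude_scale = 0.8,
                       blink_rate = 4,
                       blink_amplitude = 40,
                       iti = 4,
                       seed = 1L) {
  noise_type <- match.arg(noise_type)
  n_targets <- target_fraction * trials_per_block
  if (abs(n_targets - round(n_targets)) > 1e-9)
    stop("target_fraction * trials_per_block must be an integer ",
         "(exact prevalence per block)")
  if (target_fraction < 0 || target_fraction > 1)
    stop("target_fraction must lie in [0, 1]")
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must lie in [0, 1]")
  if (erp_attenuation_incorrect <= 0 || erp_attenuation_incorrect > 1)
    stop("erp_attenuation_incorrect must lie in (0, 1]")
  if (sampling_rate %% 32 != 0)
    stop("sampling_rate must be a multiple of 32 Hz")
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (communication_mode && n_participants %% 2 != 0)
    stop("communication_mode requires an even number of participants ",
         "(whole pairs)")
  if (conformity < 0 || conformity > 1)
    stop("conformity must lie in [0, 1]")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    target_fraction = target_fraction,
    sampling_rate = as.integer(sampling_rate),
    n_channels = as.integer(n_channels),
    error_rate = error_rate,
    rt_correct = rt_correct,
    rt_incorrect = rt_incorrect,
    erp_attenuation_incorrect = erp_attenuation_incorrect,
    communication_mode = isTRUE(communication_mode),
    confidence_noise = confidence_noise,
    confidence_coupling = confidence_coupling,
    conformity = conformity,
    noise_sd = noise_sd,
    noise_type = noise_type,
    erp_amplitude = erp_amplitude,
    erp_channels = erp_channels,
    erp_latency = erp_latency,
    erp_width = erp_width,
    resp_latency = resp_latency,
    resp_width = resp_width,
    comm_attenuation_scale = comm_attenuation_scale,
    comm_amplitude_scale = comm_amplitude_scale,
    blink_rate = blink_rate,
    blink_amplitude = blink_amplitude,
    iti = iti,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d participants, %d blocks x %d trials ",
           "(%.0f%% targets), %d ch @ %d Hz, error %.3f, comm %s, seed %d\n"),
    x$n_participants, x$n_blocks, x$trials_per_block,
    100 * x$target_fraction, x$n_channels, x$sampling_rate,
    x$error_rate, x$communication_mode, x$seed
  ))
  invisible(x)
}

# Shared stimulus-class sequence: +1 target / -1 non-target, exact
# prevalence in every block, target positions shuffled per block.
generate_stim_sequence <- function(config) {
  set.seed(config$seed %% .Machine$integer.max)
  n_t <- round(config$target_fraction * config$trials_per_block)
  unlist(lapply(seq_len(config$n_blocks), function(b) {
    s <- rep(-1, config$trials_per_block)
    s[sample.int(config$trials_per_block, n_t)] <- 1
    s
  }))
}

# Biphasic ERP template sampled at fs: positive peak at `latency`
# followed by a shallower negative rebound.
erp_template <- function(tt, latency, width) {
  exp(-((tt - latency)^2) / (2 * width^2)) -
    0.5 * exp(-((tt - latency - 1.6 * width)^2) / (2 * (1.4 * width)^2))
}

# Background noise matrix (channels x samples), white or 1/f.
background_noise <- function(n_ch, n_samp, sd, type) {
  if (type == "white") return(matrix(rnorm(n_ch * n_samp, sd = sd), n_ch))
  # pink: shape white noise by 1/sqrt(f) in the frequency domain
  t(vapply(seq_len(n_ch), function(i) {
    x <- rnorm(n_samp)
    X <- stats::fft(x)
    f <- c(1, seq_len(n_samp - 1))
    f <- pmin(f, n_samp - f + 1)  # symmetric spectrum
    X <- X / sqrt(f)
    y <- Re(stats::fft(X, inverse = TRUE)) / n_samp
    sd * y / stats::sd(y)
  }, numeric(n_samp)))
}

#' Simulate one participant's session
#'
#' Generates a continuous EEG recording plus the per-trial behavioural
#' table for one participant: background noise with a biphasic ERP
#' template injected at stimulus onset and around the response, template
#' amplitude attenuated on incorrect trials, response times drawn from
#' correctness-dependent log-normal distributions, decisions derived from
#' the stimulus class and sampled correctness, and reported confidence
#' coupled to correctness unless communication mode is on.
#'
#' @param config A \code{\link{sim_config}}.
#' @param participant Participant index (determines the per-participant
#'   random stream; the stimulus sequence is shared).
#' @param stim_seq Optional shared stimulus-class sequence (+1/-1); when
#'   \code{NULL} it is generated from \code{config$seed}.
#' @param eeg Logical; set \code{FALSE} to skip synthesis of the
#'   continuous recording and return the behavioural table only.
#' @return An object of class \code{hbci_session}: a list with
#'   \code{recording} (an \code{\link{eeg_recording}} or \code{NULL}),
#'   \code{trials} (data frame: participant, block, trial,
#'   stimulus_class, decision, correct, rt, reported_confidence,
#'   second_decision), \code{truth} (injected per-trial ERP amplitude)
#'   and \code{log} (e.g. number of resampled RT draws).
#' @examples
#' cfg <- sim_config(n_participants = 1, n_blocks = 2, trials_per_block = 8,
#'                   sampling_rate = 128, n_channels = 8, seed = 7)
#' s <- simulate_session(cfg)
#' nrow(s$trials)
#' @export
simulate_session <- function(config, participant = 1L, stim_seq = NULL,
                             eeg = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(stim_seq)) stim_seq <- generate_stim_sequence(config)
  n_trials <- config$n_blocks * config$trials_per_block
  stopifnot(length(stim_seq) == n_trials)
  set.seed((config$seed * 1009L + as.integer(participant) * 7919L) %%
             .Machine$integer.max)

  fs <- config$sampling_rate
  correct <- runif(n_trials) >= config$error_rate
  decision <- ifelse(correct, stim_seq, -stim_seq)

  # response times: log-normal, resampled when they would not fit the
  # inter-trial window (response-locked epoch must end before the next
  # trial's pre-stimulus margin)
  rt_max <- config$iti - 1.0 - 0.7 - 0.05
  rt_min <- 0.15
  rt <- numeric(n_trials)
  rt[correct] <- rlnorm(sum(correct), log(config$rt_correct$location),
                        config$rt_correct$scale)
  rt[!correct] <- rlnorm(sum(!correct), log(config$rt_incorrect$location),
                         config$rt_incorrect$scale)
  n_resampled <- 0L
  bad <- which(rt > rt_max | rt < rt_min)
  while (length(bad) > 0L) {
    n_resampled <- n_resampled + length(bad)
    p <- ifelse(correct[bad], config$rt_correct$location,
                config$rt_incorrect$location)
    s <- ifelse(correct[bad], config$rt_correct$scale,
                config$rt_incorrect$scale)
    rt[bad] <- rlnorm(length(bad), log(p), s)
    bad <- bad[rt[bad] > rt_max | rt[bad] < rt_min]
  }

  # reported confidence (0-100 in steps of 10)
  if (config$communication_mode) {
    latent <- 60 + rnorm(n_trials, sd = config$confidence_noise)
  } else {
    latent <- 60 + 15 * config$confidence_coupling * ifelse(correct, 1, -1) +
      rnorm(n_trials, sd = config$confidence_noise)
  }
  conf <- pmin(100, pmax(0, 10 * round(latent / 10)))

  # ERP amplitude ground truth
  atten <- config$erp_attenuation_incorrect
  amp_scale <- 1
  if (config$communication_mode) {
    atten <- 1 - (1 - atten) * config$comm_attenuation_scale
    amp_scale <- config$comm_amplitude_scale
  }
  amp <- amp_scale * config$erp_amplitude * ifelse(correct, 1, atten)

  trials <- data.frame(
    participant = as.integer(participant),
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    trial = seq_len(n_trials),
    stimulus_class = stim_seq,
    decision = decision,
    correct = correct,
    rt = rt,
    reported_confidence = conf,
    second_decision = NA_real_
  )

  pad <- 2.0
  stim_s <- round((pad + (seq_len(n_trials) - 1) * config$iti + 1.0) * fs) + 1L
  resp_s <- stim_s + round(rt * fs)
  recording <- NULL
  if (eeg) {
    n_samp <- round((pad * 2 + n_trials * config$iti) * fs)
    channels <- c(montage_channels(config$n_channels), earlobe_channels())
    n_ch <- length(channels)
    sig <- background_noise(n_ch, n_samp, config$noise_sd, config$noise_type)

    # ERP templates on the configured scalp channels: accumulate one
    # shared additive track, then add it to all template channels at once
    erp_idx <- match(intersect(config$erp_channels, channels), channels)
    tt_s <- seq(0, 1.5, by = 1 / fs)
    tpl_s <- erp_template(tt_s, config$erp_latency, config$erp_width)
    tt_r <- seq(-0.75, 0.75, by = 1 / fs)
    tpl_r <- erp_template(tt_r, config$resp_latency, config$resp_width)
    track <- numeric(n_samp)
    add_tpl <- function(at, tpl, a) {
      idx <- at + seq_along(tpl) - 1L
      keep <- idx >= 1L & idx <= n_samp
      track[idx[keep]] <<- track[idx[keep]] + a * tpl[keep]
    }
    for (i in seq_len(n_trials)) {
      add_tpl(stim_s[i], tpl_s, amp[i])
      add_tpl(resp_s[i] - round(0.75 * fs), tpl_r, amp[i])
    }
    sig[erp_idx, ] <- sig[erp_idx, , drop = FALSE] +
      matrix(track, length(erp_idx), n_samp, byrow = TRUE)

    # ocular blinks: strongest at Fp1/Fp2, weaker at F1/F2, faint elsewhere
    if (config$blink_rate > 0 && config$blink_amplitude > 0) {
      n_blinks <- stats::rpois(1L, config$blink_rate * n_samp / fs / 60)
      blink_len <- round(0.3 * fs)
      blink <- sin(pi * seq_len(blink_len) / blink_len)
      topo <- rep(0.1, n_ch)
      topo[match(c("Fp1", "Fp2"), channels)] <- 1
      topo[match(c("F1", "F2"), channels)] <- 0.4
      topo[match(earlobe_channels(), channels)] <- 0.05
      if (n_blinks > 0L) {
        at <- sort(sample.int(n_samp - blink_len, n_blinks))
        btrack <- numeric(n_samp)
        for (b in at) {
          idx <- b + seq_len(blink_len) - 1L
          btrack[idx] <- btrack[idx] + config$blink_amplitude * blink
        }
        sig <- sig + topo %*% t(btrack)
      }
    }

    events <- rbind(
      data.frame(kind = "stimulus_onset", sample = stim_s,
                 trial = seq_len(n_trials)),
      data.frame(kind = "response", sample = resp_s,
                 trial = seq_len(n_trials))
    )
    recording <- eeg_recording(sig, channels, fs, events)
  }

  structure(
    list(recording = recording, trials = trials,
         truth = list(erp_amplitude = amp, correct = correct),
         config = config,
         log = list(n_rt_resampled = n_resampled)),
    class = "hbci_session"
  )
}

#' @export
print.hbci_session <- function(x, ...) {
  cat(sprintf(
    "<hbci_session> participant %d: %d trials (%d targets), %s recording\n",
    x$trials$participant[1], nrow(x$trials),
    sum(x$trials$stimulus_class == 1),
    if (is.null(x$recording)) "no" else
      sprintf("%d ch @ %d Hz", nrow(x$recording$signal), x$recording$fs)
  ))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' All sessions share one stimulus-class sequence (as in an experiment
#' where every participant sees the same randomly generated display
#' order); correctness, response times and EEG noise are sampled
#' independently per participant. In communication mode participants are
#' paired in order (1-2, 3-4, ...) and a second response is produced: on
#' trials where a pair disagrees, with probability \code{conformity} the
#' member reporting the lower confidence adopts the partner's decision
#' (ties in reported confidence are resolved at random), so the pair
#' converges; otherwise both keep their first decision.
#'
#' @inheritParams simulate_session
#' @return An object of class \code{hbci_cohort}: a list of
#'   \code{hbci_session} objects with attributes \code{stim_seq} and
#'   \code{pairs} (two-column matrix of paired participant indices, or
#'   \code{NULL}).
#' @examples
#' cfg <- sim_config(n_participants = 2, n_blocks = 1, trials_per_block = 8,
#'                   sampling_rate = 128, n_channels = 8)
#' ch <- simulate_cohort(cfg, eeg = FALSE)
#' length(ch)
#' @export
simulate_cohort <- function(config, eeg = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stim_seq <- generate_stim_sequence(config)
  sessions <- lapply(seq_len(config$n_participants), function(p)
    simulate_session(config, participant = p, stim_seq = stim_seq, eeg = eeg))

  pairs <- NULL
  if (config$communication_mode) {
    pairs <- matrix(seq_len(config$n_participants), ncol = 2, byrow = TRUE)
    set.seed((config$seed * 31L + 17L) %% .Machine$integer.max)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      da <- sessions[[a]]$trials$decision
      db <- sessions[[b]]$trials$decision
      ca <- sessions[[a]]$trials$reported_confidence
      cb <- sessions[[b]]$trials$reported_confidence
      sa <- da; sb <- db
      dis <- which(da != db)
      conv <- dis[runif(length(dis)) < config$conformity]
      for (i in conv) {
        yielder <- if (ca[i] < cb[i]) "a" else if (cb[i] < ca[i]) "b" else
          sample(c("a", "b"), 1L)
        if (yielder == "a") sa[i] <- db[i] else sb[i] <- da[i]
      }
      sessions[[a]]$trials$second_decision <- sa
      sessions[[b]]$trials$second_decision <- sb
    }
  }
  structure(sessions, stim_seq = stim_seq, pairs = pairs,
            class = "hbci_cohort")
}

#' @export
print.hbci_cohort <- function(x, ...) {
  cat(sprintf("<hbci_cohort> %d participants, %d trials each%s\n",
              length(x), nrow(x[[1]]$trials),
              if (is.null(attr(x, "pairs"))) "" else
                sprintf(", %d communicating pairs", nrow(attr(x, "pairs")))))
  invisible(x)
}
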
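test_that("earlobe re-referencing subtracts the per-sample reference mean", {
  # 1 scalp + 2 earlobe channels, 4 samples, hand-computed subtraction
  sig <- rbind(Fp1 = c(5, 6, 7, 8),
               A1 = c(1, 2, 3, 4),
               A2 = c(3, 2, 1, 0))
  rec <- eeg_recording(sig, c("Fp1", "A1", "A2"), 128,
                       data.frame(kind = "stimulus_onset", sample = 2,
                                  trial = 1))
  out <- rereference_earlobes(rec)
  expect_equal(unname(out$signal["Fp1", ]), c(5 - 2, 6 - 2, 7 - 2, 8 - 2))
  expect_true(all(out$signal[c("A1", "A2"), ] == 0))

  # constant reference: scalp shifted by the constant
  sig2 <- rbind(Cz = c(10, 11), A1 = c(3, 3), A2 = c(3, 3))
  rec2 <- eeg_recording(sig2, c("Cz", "A1", "A2"), 128,
                        data.frame(kind = "stimulus_onset", sample = 1,
                                   trial = 1))
  expect_equal(unname(rereference_earlobes(rec2)$signal["Cz", ]), c(7, 8))

  # zero reference leaves scalp unchanged; re-referencing is idempotent
  sig3 <- rbind(Cz = c(1, 2, 3), A1 = 0, A2 = 0)
  rec3 <- eeg_recording(sig3, c("Cz", "A1", "A2"), 128,
                        data.frame(kind = "stimulus_onset", sample = 1,
                                   trial = 1))
  once <- rereference_earlobes(rec3)
  expect_equal(unname(once$signal["Cz", ]), c(1, 2, 3))
  twice <- rereference_earlobes(once)
  expect_identical(once$signal, twice$signal)

  expect_error(rereference_earlobes(
    eeg_recording(matrix(0, 1, 4), "Cz", 128,
                  data.frame(kind = "stimulus_onset", sample = 1,
                             trial = 1))), "missing")
})

test_that("band-pass keeps the pass band and rejects DC and high frequency", {
  fs <- 512
  t <- seq(0, 30, by = 1 / fs)[-1]
  mk <- function(x) toy_recording(n_ch = 8, n_samp = length(t), fs = fs,
                                  signal = matrix(rep(x, each = 10),
                                                  10, length(t)))
  # 10 Hz tone passes within 5%
  rec <- bandpass_filter(mk(sin(2 * pi * 10 * t)))
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  a10 <- tone_amplitude(rec$signal[1, mid], 10, fs)
  expect_lt(abs(a10 - 1), 0.05)
  # DC is removed to below 1%
  recdc <- bandpass_filter(mk(rep(1, length(t))))
  expect_lt(max(abs(recdc$signal[1, mid])), 0.01)
  # 100 Hz (beyond the 40 Hz edge) is attenuated to below 1%
  rec100 <- bandpass_filter(mk(sin(2 * pi * 100 * t)))
  expect_lt(tone_amplitude(rec100$signal[1, mid], 100, fs), 0.01)
})

test_that("ocular regression removes the proxy component", {
  fs <- 128
  n <- 4096
  set.seed(42)
  blink <- 5 * sin(2 * pi * 0.8 * seq_len(n) / fs)
  sig <- matrix(rnorm(10 * n), 10, n)
  channels <- c(montage_channels(8), earlobe_channels())
  # blink enters Fp1/Fp2 fully, F1/F2 partially -> proxy o recovers it
  sig[1, ] <- sig[1, ] + blink        # Fp1
  sig[3, ] <- sig[3, ] + blink        # Fp2
  sig[2, ] <- sig[2, ] + 0.3 * blink  # F1
  sig[4, ] <- sig[4, ] + 0.3 * blink  # F2
  o <- ((sig[1, ] - sig[2, ]) + (sig[3, ] - sig[4, ])) / 2
  # a channel constructed as 0.8 * o + independent noise
  sig[5, ] <- 0.8 * o + rnorm(n)
  # a channel empirically orthogonal to the proxy
  ortho <- rnorm(n)
  ortho <- ortho - sum(ortho * (o - mean(o))) / sum((o - mean(o))^2) *
    (o - mean(o))
  sig[6, ] <- ortho
  rec <- toy_recording(n_ch = 8, n_samp = n, fs = fs, signal = sig)
  out <- remove_ocular(rec)
  expect_lt(abs(cor(out$signal[5, ], o)), 0.05)
  expect_equal(out$signal[6, ], sig[6, ], tolerance = 1e-8)
  # all channels end up decorrelated from the proxy
  expect_true(all(abs(apply(out$signal[1:8, ], 1, cor, y = o)) < 0.05))

  # degenerate proxy: recording unchanged, with a warning
  sig0 <- matrix(rnorm(10 * 256), 10, 256)
  sig0[2, ] <- sig0[1, ]  # F1 == Fp1
  sig0[4, ] <- sig0[3, ]  # F2 == Fp2
  rec0 <- toy_recording(n_ch = 8, n_samp = 256, fs = fs, signal = sig0)
  expect_warning(out0 <- remove_ocular(rec0), "zero variance")
  expect_identical(out0$signal, rec0$signal)
})

test_that("epoch windows use the specified offsets and bounds", {
  fs <- 2048
  geom_trim <- round(0.2 * fs)            # 410 samples
  n_raw <- 48 * (fs / 32) + 2 * geom_trim # 3892 samples
  n <- 6 * fs
  sig <- matrix(rnorm(4 * n), 4, n)
  rec <- eeg_recording(sig, c("Fp1", "F1", "Fp2", "F2"), fs,
                       data.frame(kind = c("stimulus_onset", "response"),
                                  sample = c(8193, 10241),  # 4.0 s, 5.0 s
                                  trial = 1))
  ep <- extract_epochs(rec)
  # stimulus-locked window starts 200 ms before onset: 3.8 s
  expect_equal(dim(ep$stimulus), c(4, n_raw, 1))
  expect_equal(unname(ep$stimulus[, 1, 1]), sig[, 8193 - geom_trim])
  # response-locked window starts 1200 ms before the response: 3.8 s
  expect_equal(unname(ep$response[, 1, 1]), sig[, 10241 - round(1.2 * fs)])
  expect_equal(nrow(ep$excluded), 0L)

  # a stimulus too close to the recording start is excluded and counted
  rec2 <- eeg_recording(sig, c("Fp1", "F1", "Fp2", "F2"), fs,
                        data.frame(kind = "stimulus_onset",
                                   sample = round(0.05 * fs),
                                   trial = 1))
  ep2 <- extract_epochs(rec2)
  expect_equal(nrow(ep2$excluded), 1L)
  expect_equal(dim(ep2$stimulus)[3], 0L)
})

test_that("conditioning yields exactly 48 samples per channel at 32 Hz", {
  fs <- 256
  geom <- 48 * (fs / 32) + 2 * round(0.2 * fs)
  t <- (seq_len(geom) - 1) / fs
  # 4 Hz passes (within 10%), 30 Hz is suppressed (>= 95%) even though it
  # would alias to 2 Hz after decimation
  x <- matrix(rep(sin(2 * pi * 4 * t) + sin(2 * pi * 30 * t), each = 3),
              3, geom)
  out <- condition_epoch(x, fs)
  expect_equal(dim(out), c(3, 48))
  expect_equal(attr(out, "fs"), 32)
  expect_equal(length(attr(out, "times")), 48)
  expect_equal(diff(range(attr(out, "times"))), 1.5 - 1 / 32)
  a4 <- tone_amplitude(out[1, ], 4, 32)
  a2 <- tone_amplitude(out[1, ], 2, 32)   # the 30 Hz alias location
  expect_lt(abs(a4 - 1), 0.1)
  expect_lt(a2, 0.05)

  # a pure linear ramp is removed by detrending
  ramp <- matrix(rep(seq(-1, 1, length.out = geom), each = 2), 2, geom)
  out_r <- condition_epoch(ramp, fs)
  expect_lt(max(abs(out_r)), 1e-6)

  # wrong input length is rejected
  expect_error(condition_epoch(matrix(0, 2, geom - 1), fs), "samples")
})

test_that("conditioning is linear in the input", {
  fs <- 128
  geom <- 48 * (fs / 32) + 2 * round(0.2 * fs)
  set.seed(9)
  x <- matrix(rnorm(4 * geom), 4, geom)
  expect_equal(condition_epoch(3.7 * x, fs), 3.7 * condition_epoch(x, fs),
               tolerance = 1e-10)
})

test_that("filter order does not affect artefact regression beyond tolerance", {
  # band-pass then ocular removal vs the reverse order agree closely on
  # simulated data (regression guard, not an exact identity)
  cfg <- sim_config(n_participants = 1, n_blocks = 1, trials_per_block = 12,
                    sampling_rate = 128, n_channels = 8, seed = 13)
  s <- simulate_session(cfg)
  r0 <- rereference_earlobes(s$recording)
  a <- remove_ocular(bandpass_filter(r0))
  b <- bandpass_filter(remove_ocular(r0))
  mid <- seq(2000, ncol(a$signal) - 2000)
  scale <- sd(a$signal[5, mid])
  expect_lt(mean(abs(a$signal[5, mid] - b$signal[5, mid])) / scale, 0.1)
})

test_that("session preprocessing returns the full epoch set", {
  cfg <- sim_config(n_participants = 1, n_blocks = 1, trials_per_block = 12,
                    sampling_rate = 128, n_channels = 8, seed = 17)
  s <- simulate_session(cfg)
  pp <- preprocess_session(s)
  expect_s3_class(pp, "processed_session")
  expect_equal(dim(pp$stimulus), c(8, 48, 12))
  expect_equal(dim(pp$response), c(8, 48, 12))
  expect_equal(pp$channels, montage_channels(8))
  expect_equal(nrow(pp$excluded), 0L)
  # batch conditioning equals the per-epoch operation
  rec <- remove_ocular(bandpass_filter(rereference_earlobes(s$recording)))
  raw <- extract_epochs(rec)
  expect_equal(pp$stimulus[, , 4], condition_epoch(raw$stimulus[, , 4], 128),
               ignore_attr = TRUE)
})
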
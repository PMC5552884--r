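#' Standard 10-20 scalp montage used by the simulator
#'
#' Returns the first \code{n} labels of a fixed 64-channel montage named
#' according to the international 10-20 (extended 10-10) system. The
#' ordering is chosen so that reduced montages always retain the channels
#' the pipeline depends on: the ocular-regression sites (Fp1, F1, Fp2, F2)
#' come first, followed by the midline centro-parietal sites where the
#' simulator injects its event-related template (Cz, CPz, Pz, POz).
#'
#' @param n Number of scalp channels (1 to 64).
#' @return Character vector of \code{n} channel labels.
#' @examples
#' montage_channels(8)
#' @export
montage_channels <- function(n = 64) {
  labs <- c(
    "Fp1", "F1", "Fp2", "F2", "Cz", "CPz", "Pz", "POz",
    "Fz", "FCz", "Oz", "Fpz", "AFz", "F3", "F4", "F5",
    "F6", "F7", "F8", "FC1", "FC2", "FC3", "FC4", "FC5",
    "FC6", "FT7", "FT8", "C1", "C2", "C3", "C4", "C5",
    "C6", "T7", "T8", "CP1", "CP2", "CP3", "CP4", "CP5",
    "CP6", "TP7", "TP8", "P1", "P2", "P3", "P4", "P5",
    "P6", "P7", "P8", "PO3", "PO4", "PO7", "PO8", "O1",
    "O2", "AF3", "AF4", "AF7", "AF8", "F9", "F10", "Iz"
  )
  stopifnot(length(labs) == 64L)
  if (n < 1L || n > 64L) stop("n must be between 1 and 64")
  labs[seq_len(n)]
}

#' @rdname montage_channels
#' @details \code{earlobe_channels()} returns the two reference labels
#'   appended to every simulated recording.
#' @export
earlobe_channels <- function() c("A1", "A2")
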
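# shared internal helpers

# typed condition for degenerate (single-class) training sets so callers
# can fall back to constant weights
stop_degenerate <- function(msg) {
  stop(structure(
    class = c("hbci_degenerate_training", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Stratified random partition of n items into k near-equal folds; items
# are shuffled within each stratum and dealt round-robin. Returns an
# integer fold assignment of length n. Uses the current RNG stream.
stratified_fold_assignment <- function(n, k, strata = NULL) {
  if (k > n) stop("more folds than items")
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  fold <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    # continue the round-robin across strata so fold sizes balance
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}
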
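#' Weighted-majority group decision for one trial
#'
#' Aggregates the +/-1 decisions of a group by the weighted majority
#' rule: the group decision is the sign of the confidence-weighted sum
#' of member decisions. An exactly zero sum is a tie and is resolved by
#' a fair coin flip (uniform random +/-1) from the supplied tie-break
#' draw or the current RNG stream.
#'
#' @param decisions Vector of member decisions, each +1 or -1.
#' @param weights Vector of non-negative member weights (same length).
#' @param tiebreak Optional uniform(0, 1) draw used only on ties
#'   (\code{< 0.5} gives +1); when \code{NULL} one draw is taken from
#'   the current RNG.
#' @return A list: \code{decision} (+1/-1), \code{tie} (logical),
#'   \code{score} (the weighted sum).
#' @examples
#' weighted_group_decision(c(1, -1), c(0.9, 0.2))$decision
#' @export
weighted_group_decision <- function(decisions, weights, tiebreak = NULL) {
  if (length(decisions) == 0L) stop("empty group")
  if (length(decisions) != length(weights))
    stop("decisions and weights must have equal length")
  if (!all(decisions %in% c(-1, 1))) stop("decisions must be +1 or -1")
  if (any(weights < 0)) stop("weights must be non-negative")
  score <- sum(weights * decisions)
  if (score != 0)
    return(list(decision = sign(score), tie = FALSE, score = score))
  u <- if (is.null(tiebreak)) runif(1L) else tiebreak
  list(decision = if (u < 0.5) 1 else -1, tie = TRUE, score = 0)
}

#' Enumerate all groups of a given size
#'
#' All \code{choose(n, m)} distinct subsets of \code{m} participants out
#' of \code{n}, each exactly once, in deterministic lexicographic order
#' (10 participants give 45 groups of size 2, 120 of size 3, ...).
#'
#' @param n Number of participants.
#' @param m Group size.
#' @return List of integer member vectors.
#' @examples
#' length(enumerate_groups(10, 2))
#' @export
enumerate_groups <- function(n, m) {
  if (m < 1L || m > n) stop("group size must satisfy 1 <= m <= n")
  g <- combn(n, m, simplify = FALSE)
  lapply(g, as.integer)
}

#' Enumerate pair-preserving groups
#'
#' Combines whole communicating pairs into groups: all
#' \code{choose(n_pairs, k)} unions of \code{k} pairs, so no group splits
#' a pair and only even sizes \code{2k} occur (7 pairs give 21 groups of
#' size 4 and 35 of size 6).
#'
#' @param pairs Two-column matrix of participant indices, one pair per
#'   row (or a list of 2-vectors).
#' @param k Number of pairs per group.
#' @return List of integer member vectors of length \code{2k}.
#' @examples
#' p <- matrix(1:14, ncol = 2, byrow = TRUE)
#' length(enumerate_pair_groups(p, 2))
#' @export
enumerate_pair_groups <- function(pairs, k) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  np <- nrow(pairs)
  if (k < 1L || k > np)
    stop("number of pairs per group must satisfy 1 <= k <= ", np)
  combn(np, k, simplify = FALSE) |>
    lapply(function(ix) as.integer(t(pairs[ix, , drop = FALSE])))
}

#' Evaluate a decision method over enumerated groups
#'
#' Applies the weighted majority rule trial-by-trial for every group and
#' returns per-group error rates against the ground truth. Tie-break
#' draws come from one seeded generator with draw order fixed by (group
#' index, trial index), so runs are bit-reproducible for a given seed
#' regardless of how many ties occur.
#'
#' @param groups List of member index vectors (see
#'   \code{\link{enumerate_groups}}).
#' @param decisions Participants x trials matrix of +/-1 decisions.
#' @param weights Participants x trials matrix of non-negative weights
#'   (all 1 for standard majority; estimated confidence for the
#'   BCI-assisted methods; raw 0-100 reported confidence for confidence
#'   majority).
#' @param truth Length-trials vector of correct decisions (+/-1).
#' @param seed Integer seed for the tie-break generator.
#' @return Data frame with one row per group: \code{group} (id),
#'   \code{size}, \code{error_rate}, \code{n_ties}.
#' @export
evaluate_group_method <- function(groups, decisions, weights, truth,
                                  seed = 1L) {
  stopifnot(is.matrix(decisions), is.matrix(weights),
            all(dim(decisions) == dim(weights)),
            ncol(decisions) == length(truth))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!all(decisions %in% c(-1, 1))) stop("decisions must be +1 or -1")
  n_trials <- ncol(decisions)
  wd <- weights * decisions
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    if (length(members) == 0L) stop("empty group")
    score <- .colSums(wd[members, , drop = FALSE], length(members), n_trials)
    G <- sign(score)
    # one draw per trial, in trial order, whether or not it is needed:
    # keeps the (group, trial) draw order fixed
    u <- runif(n_trials)
    tie <- score == 0
    G[tie] <- ifelse(u[tie] < 0.5, 1, -1)
    out[[g]] <- data.frame(
      group = g, size = length(members),
      error_rate = mean(G != truth), n_ties = sum(tie))
  }
  do.call(rbind, out)
}
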
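# Independent brute-force oracles shared across test files. These stay
# deliberately naive (enumeration / grid refinement) so they cannot share
# a code path with the implementation they check.

# exact one-sided signed-rank p-value by enumeration of all 2^n sign
# assignments over the ranks of |d| (requires no ties, no zeros)
wsr_exact_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mean(v_all <= v_obs)   # P(V <= v_obs), "less" alternative
}

# iterative grid refinement of the L2-penalised logistic loss
# (intercept unpenalised) for one standardised feature
grid_logistic <- function(z, y, C, rounds = 4, span = 4, k = 41) {
  loss <- function(b0, b1) {
    eta <- b0 + b1 * z
    sum(log1p(exp(-abs(y * eta))) + pmax(-y * eta, 0)) + b1^2 / (2 * C)
  }
  c0 <- c1 <- 0
  for (r in seq_len(rounds)) {
    g0 <- seq(c0 - span, c0 + span, length.out = k)
    g1 <- seq(c1 - span, c1 + span, length.out = k)
    vals <- outer(g0, g1, Vectorize(loss))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c0 <- g0[ix[1]]; c1 <- g1[ix[2]]
    span <- span * 2.5 / (k - 1)
  }
  c(intercept = c0, coef = c1)
}

# tie-corrected Kruskal-Wallis H computed from first principles
kw_hand_h <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n <- length(all_v)
  groups <- list(seq_along(x), length(x) + seq_along(y))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) sum(r[g])^2 / length(g), 0)) -
    3 * (n + 1)
  ties <- table(all_v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
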
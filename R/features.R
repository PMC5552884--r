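#' Fit a Common Spatial Patterns transformation
#'
#' Solves the two-class CSP problem on conditioned epochs labelled by
#' decision correctness. Per-trial covariance matrices are normalised by
#' their trace and averaged within class; the transformation is the
#' solution of the generalized eigendecomposition of the class
#' covariances, with rows sorted by decreasing variance ratio of the
#' "confident" (correct) class, so the first spatial filter captures the
#' pattern whose variance best separates the classes. When the composite
#' covariance is ill-conditioned, both class estimates are shrunk toward
#' a scaled identity with an analytic (Ledoit-Wolf style) intensity.
#'
#' @param epochs Channels x samples x trials array of conditioned epochs.
#' @param labels Logical vector (one per trial): \code{TRUE} for correct
#'   ("confident") trials.
#' @param shrink \code{"auto"} (shrink only when ill-conditioned),
#'   \code{"never"} or \code{"always"}.
#' @return An object of class \code{csp_model}: \code{W} (filters x
#'   channels transformation, first row = maximal confident-class
#'   variance ratio), \code{ratios} (per-filter confident-class variance
#'   ratios, in \code{[0, 1]}, pairwise diagonals summing to 1),
#'   \code{cov_confident}, \code{cov_nonconfident}, \code{shrinkage}.
#' @examples
#' x <- array(rnorm(4 * 48 * 20), c(4, 48, 20))
#' m <- fit_csp(x, rep(c(TRUE, FALSE), 10))
#' m$ratios
#' @export
fit_csp <- function(epochs, labels, shrink = c("auto", "never", "always")) {
  shrink <- match.arg(shrink)
  stopifnot(length(dim(epochs)) == 3L, dim(epochs)[3] == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop_degenerate("CSP requires trials from both classes")
  if (min(table(labels)) < 2L)
    stop_degenerate("CSP requires at least 2 trials per class")

  covs <- trial_covariances(epochs)
  avg <- function(idx) Reduce(`+`, covs[idx]) / length(idx)
  s1 <- avg(which(labels))    # confident / correct
  s2 <- avg(which(!labels))   # non-confident / incorrect

  gamma <- 0
  sc <- s1 + s2
  ill <- rcond_sym(sc) < 1e-10
  if (shrink == "always" || (shrink == "auto" && ill)) {
    gamma <- lw_shrinkage(covs, (s1 + s2) / 2)
    s1 <- shrink_cov(s1, gamma)
    s2 <- shrink_cov(s2, gamma)
    sc <- s1 + s2
  }

  # whiten the composite covariance, then eigendecompose the whitened
  # confident-class covariance
  ec <- eigen(sc, symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-12
  P <- ec$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ec$values[keep]), sum(keep)) %*%
    t(ec$vectors[, keep, drop = FALSE])
  M <- P %*% s1 %*% P
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  W <- t(em$vectors) %*% P
  ord <- order(em$values, decreasing = TRUE)
  structure(
    list(W = W[ord, , drop = FALSE], ratios = em$values[ord],
         cov_confident = s1, cov_nonconfident = s2, shrinkage = gamma),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf(
    "<csp_model> %d filters, leading confident-class variance ratio %.3f (shrinkage %.3g)\n",
    nrow(x$W), x$ratios[1], x$shrinkage))
  invisible(x)
}

# per-trial trace-normalised covariances
trial_covariances <- function(epochs) {
  n <- dim(epochs)[3]
  lapply(seq_len(n), function(i) {
    x <- epochs[, , i, drop = FALSE]
    dim(x) <- dim(epochs)[1:2]
    x <- x - rowMeans(x)
    s <- tcrossprod(x) / (ncol(x) - 1L)
    tr <- sum(diag(s))
    if (tr <= 0) s else s / tr
  })
}

rcond_sym <- function(s) {
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# Ledoit-Wolf style shrinkage intensity for a mean of per-trial
# covariances toward nu * I: b^2 / d^2 capped at 1.
lw_shrinkage <- function(covs, sbar) {
  p <- nrow(sbar)
  nu <- sum(diag(sbar)) / p
  d2 <- sum((sbar - diag(nu, p))^2)
  if (d2 <= 0) return(0)
  n <- length(covs)
  b2 <- sum(vapply(covs, function(ci) sum((ci - sbar)^2), 0)) / n^2
  min(1, b2 / d2)
}

shrink_cov <- function(s, gamma) {
  nu <- sum(diag(s)) / nrow(s)
  (1 - gamma) * s + gamma * diag(nu, nrow(s))
}

#' Log-variance of the leading CSP projection
#'
#' Projects an epoch on the model's first spatial filter and returns the
#' natural logarithm of the projection's sample variance (the neural
#' feature). Variances are floored at 1e-12 before the log.
#'
#' @param epoch Channels x samples matrix (or channels x samples x trials
#'   array, giving one value per trial).
#' @param model A \code{\link{fit_csp}} model with matching channel count.
#' @return Numeric scalar (or vector for an array input).
#' @export
apply_csp_logvar <- function(epoch, model) {
  stopifnot(inherits(model, "csp_model"))
  w1 <- model$W[1, ]
  if (is.matrix(epoch)) {
    if (nrow(epoch) != length(w1))
      stop("epoch channel count does not match the CSP model")
    proj <- drop(w1 %*% epoch)
    return(log(max(var(proj), 1e-12)))
  }
  stopifnot(length(dim(epoch)) == 3L, dim(epoch)[1] == length(w1))
  n <- dim(epoch)[3]
  vapply(seq_len(n), function(i) {
    proj <- drop(w1 %*% epoch[, , i])
    log(max(var(proj), 1e-12))
  }, 0)
}

#' Assemble a per-trial feature vector
#'
#' Combines the stimulus-locked and response-locked neural features
#' (CSP log-variances) and the behavioural response time according to
#' the requested weighting mode: response times only (\code{rt_only}),
#' neural features only (\code{nf_only}) or both (\code{hybrid}).
#'
#' @param nf_stimulus,nf_response Neural features (log-variance,
#'   dimensionless); may be \code{NULL}/\code{NA} only if the mode does
#'   not require them.
#' @param rt Response time in seconds (required unless \code{nf_only}).
#' @param mode One of \code{"rt_only"}, \code{"nf_only"},
#'   \code{"hybrid"}.
#' @return Named numeric vector: \code{rt}; \code{nf_stimulus},
#'   \code{nf_response}; or all three.
#' @export
build_feature_vector <- function(nf_stimulus = NULL, nf_response = NULL,
                                 rt = NULL,
                                 mode = c("hybrid", "rt_only", "nf_only")) {
  mode <- match.arg(mode)
  need <- switch(mode,
                 rt_only = list(rt = rt),
                 nf_only = list(nf_stimulus = nf_stimulus,
                                nf_response = nf_response),
                 hybrid = list(nf_stimulus = nf_stimulus,
                               nf_response = nf_response, rt = rt))
  bad <- names(need)[vapply(need, function(v)
    is.null(v) || anyNA(v) || !all(is.finite(v)), TRUE)]
  if (length(bad) > 0)
    stop("missing or non-finite feature(s) for mode '", mode, "': ",
         paste(bad, collapse = ", "))
  if (!is.null(rt) && mode != "nf_only" && any(rt <= 0))
    stop("rt must be positive")
  n <- unique(lengths(need))
  if (length(n) != 1L) stop("feature inputs must have equal length")
  out <- do.call(cbind, need)
  if (n == 1L) drop(out)[names(need)] else out
}
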
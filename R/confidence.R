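# L2-penalised logistic confidence model.
#
# Label convention: correct decisions are the "confident" class with
# label -1, incorrect decisions are "non-confident" with label +1. The
# model predicts P(non-confident); the confidence weight w is the
# probability of the confident/correct class, w = logistic(-(b0 + x'b)).

# Newton-Raphson fit of the penalised logistic loss
#   sum_i log(1 + exp(-y_i (b0 + x_i'b))) + ||b||^2 / (2C)
# with y in {-1, +1} and an unpenalised intercept. The problem is
# strictly convex; step-halving guards the few hard cases (e.g. perfect
# separation at large C, where the penalty still bounds the optimum).
logistic_ridge_fit <- function(X, y, C, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  pen <- c(0, rep(1 / C, p))        # intercept unpenalised
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    sum(log1p(exp(-abs(y * eta))) + pmax(-y * eta, 0)) +
      sum(pen * b^2) / 2
  }
  f0 <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- plogis(y * eta)                    # P(correct side)
    grad <- drop(crossprod(Xa, -y * (1 - mu))) + pen * beta
    wgt <- mu * (1 - mu)
    H <- crossprod(Xa * wgt, Xa) + diag(pen, p + 1L)
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p + 1L), grad))
    t_ <- 1
    repeat {
      bn <- beta - t_ * step
      fn <- obj(bn)
      if (fn <= f0 + 1e-12 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    conv <- abs(f0 - fn) < tol * (abs(f0) + 1)
    beta <- bn; f0 <- fn
    if (conv) break
  }
  list(intercept = beta[1], coef = beta[-1], value = f0)
}

# mean logistic loss of predictions p (probability of y = +1) against
# labels y in {-1, +1}
mean_log_loss <- function(eta, y) {
  mean(log1p(exp(-abs(y * eta))) + pmax(-y * eta, 0))
}

#' Fit the logistic decision-confidence model
#'
#' Trains the correctness-labelled confidence estimator: features are
#' z-scored on training statistics, an L2-regularised logistic model is
#' fit with the regularisation strength \code{C} selected from
#' \code{10^-4, ..., 10^4} by stratified inner cross-validation (3 folds
#' by default: 288 training trials split 192 fit / 96 validate), scoring
#' by held-out logistic loss with fold-specific standardisation. Ties in
#' the mean validation loss go to the smallest \code{C} (strongest
#' regularisation). The final model is refit on all trials with the
#' selected \code{C}. Correct decisions carry label -1 ("confident"),
#' incorrect +1 ("non-confident").
#'
#' If the minority class has fewer than 2 trials the inner CV is
#' infeasible; \code{C} is fixed at 1 and the model is flagged
#' (\code{cv_fallback}). A single-class training set raises a
#' degenerate-training error (condition class
#' \code{hbci_degenerate_training}).
#'
#' @param X Numeric matrix (trials x features) or vector (one feature).
#' @param correct Logical vector of decision correctness.
#' @param C_grid Candidate regularisation strengths.
#' @param n_inner Inner fold count (reduced automatically when the
#'   minority class is smaller).
#' @return An object of class \code{confidence_model}: \code{coef},
#'   \code{intercept}, \code{C}, \code{mu}, \code{sigma} (training
#'   standardisation), \code{labels} (the label convention),
#'   \code{cv} (data frame of per-C mean validation losses),
#'   \code{inner_fold_sizes}, \code{cv_fallback}.
#' @examples
#' set.seed(1)
#' rt <- c(rnorm(30, 0.5, 0.05), rnorm(10, 1.2, 0.1))
#' m <- fit_confidence_model(rt, rep(c(TRUE, FALSE), c(30, 10)))
#' m$C
#' @export
fit_confidence_model <- function(X, correct, C_grid = 10^(-4:4),
                                 n_inner = 3L) {
  X <- as.matrix(X)
  correct <- as.logical(correct)
  stopifnot(nrow(X) == length(correct))
  if (length(unique(correct)) < 2L)
    stop_degenerate("confidence model needs both correct and incorrect trials")
  y <- ifelse(correct, -1, 1)
  n_min <- min(table(correct))

  cv_fallback <- FALSE
  cv_tab <- NULL
  fold_sizes <- integer()
  if (n_min < 2L) {
    C_sel <- 1
    cv_fallback <- TRUE
  } else {
    k <- min(n_inner, n_min)
    fold <- stratified_fold_assignment(length(y), k, strata = correct)
    losses <- matrix(NA_real_, length(C_grid), k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      st <- standardize_fit(X[tr, , drop = FALSE])
      Xtr <- standardize_apply(X[tr, , drop = FALSE], st)
      Xte <- standardize_apply(X[te, , drop = FALSE], st)
      for (ci in seq_along(C_grid)) {
        fit <- logistic_ridge_fit(Xtr, y[tr], C_grid[ci])
        eta <- drop(Xte %*% fit$coef) + fit$intercept
        losses[ci, f] <- mean_log_loss(eta, y[te])
      }
    }
    mean_loss <- rowMeans(losses)
    C_sel <- C_grid[which.min(mean_loss)]  # ties -> smallest C (grid order)
    cv_tab <- data.frame(C = C_grid, loss = mean_loss)
    fold_sizes <- as.integer(table(fold))
  }

  st <- standardize_fit(X)
  fit <- logistic_ridge_fit(standardize_apply(X, st), y, C_sel)
  structure(
    list(coef = fit$coef, intercept = fit$intercept, C = C_sel,
         mu = st$mu, sigma = st$sigma,
         labels = c(confident = -1, nonconfident = 1),
         cv = cv_tab, inner_fold_sizes = fold_sizes,
         cv_fallback = cv_fallback),
    class = "confidence_model"
  )
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf(
    "<confidence_model> %d feature(s), C = %g%s\n", length(x$coef), x$C,
    if (x$cv_fallback) " (inner CV infeasible, default C)" else ""))
  invisible(x)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sigma, "/")
}

#' Estimate the confidence weight of a decision
#'
#' Applies a fitted confidence model to one or more feature vectors and
#' returns \code{w}, the predicted probability that the decision is
#' correct (the "confident" class): \code{w = logistic(-(b0 + z'b))}
#' with \code{z} the training-standardised features. Deterministic.
#'
#' @param model A \code{\link{fit_confidence_model}} or
#'   \code{\link{constant_confidence_model}} object.
#' @param X Feature vector (length = model features) or matrix
#'   (trials x features).
#' @return Numeric vector of weights in \code{[0, 1]}.
#' @export
estimate_confidence <- function(model, X) {
  if (inherits(model, "constant_confidence_model"))
    return(rep(model$w, if (is.matrix(X)) nrow(X) else 1L))
  stopifnot(inherits(model, "confidence_model"))
  if (!is.matrix(X)) X <- matrix(X, ncol = length(model$coef))
  if (ncol(X) != length(model$coef))
    stop("feature dimensionality does not match the model")
  if (!all(is.finite(X))) stop("non-finite feature value")
  Z <- standardize_apply(X, list(mu = model$mu, sigma = model$sigma))
  eta <- drop(Z %*% model$coef) + model$intercept
  plogis(-eta)
}

#' Constant-weight fallback model
#'
#' Used when a participant's training set is degenerate (single class):
#' every decision receives the same weight so group evaluation can
#' proceed.
#'
#' @param w The constant weight (default 1).
#' @return An object of class \code{constant_confidence_model}.
#' @export
constant_confidence_model <- function(w = 1) {
  stopifnot(w >= 0, w <= 1)
  structure(list(w = w), class = "constant_confidence_model")
}
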
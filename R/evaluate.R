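#' Build outer cross-validation folds
#'
#' Random partition of trials into near-equal folds, optionally
#' stratified (e.g. by stimulus class so every test fold keeps the
#' design prevalence). With 320 trials and 10 folds every fold has 288
#' training and 32 test trials. The same folds are shared by all
#' participants of a run so groups are evaluated on common test trials.
#'
#' @param n_trials Number of trials.
#' @param n_folds Number of folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @param strata Optional stratification vector of length
#'   \code{n_trials}.
#' @return List of \code{fold_split} lists with elements \code{fold},
#'   \code{train}, \code{test}.
#' @examples
#' f <- make_folds(320, 10, seed = 1)
#' lengths(f[[1]][c("train", "test")])
#' @export
make_folds <- function(n_trials, n_folds = 10L, seed = NULL, strata = NULL) {
  if (n_folds > n_trials) stop("more folds than trials")
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  fold <- stratified_fold_assignment(n_trials, n_folds, strata)
  lapply(seq_len(n_folds), function(f)
    list(fold = f, train = which(fold != f), test = which(fold == f)))
}

# internal: CSP fit from precomputed per-trial covariances (same maths
# as fit_csp, which recomputes covariances from epochs)
fit_csp_from_covs <- function(covs, labels, shrink = "auto") {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop_degenerate("CSP requires at least 2 trials per class")
  avg <- function(idx) Reduce(`+`, covs[idx]) / length(idx)
  s1 <- avg(which(labels)); s2 <- avg(which(!labels))
  gamma <- 0
  sc <- s1 + s2
  if (shrink == "always" || (shrink == "auto" && rcond_sym(sc) < 1e-10)) {
    gamma <- lw_shrinkage(covs, (s1 + s2) / 2)
    s1 <- shrink_cov(s1, gamma); s2 <- shrink_cov(s2, gamma)
    sc <- s1 + s2
  }
  ec <- eigen(sc, symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-12
  P <- ec$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ec$values[keep]), sum(keep)) %*%
    t(ec$vectors[, keep, drop = FALSE])
  M <- P %*% s1 %*% P; M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  W <- t(em$vectors) %*% P
  ord <- order(em$values, decreasing = TRUE)
  structure(list(W = W[ord, , drop = FALSE], ratios = em$values[ord],
                 cov_confident = s1, cov_nonconfident = s2,
                 shrinkage = gamma),
            class = "csp_model")
}

# log-variance of the first-filter projection for all epochs at once;
# flat is channels x (48 * n_trials)
logvar_all <- function(flat, w1) {
  proj <- matrix(drop(w1 %*% flat), nrow = 48L)
  v <- (colSums(proj^2) - 48 * colMeans(proj)^2) / 47
  log(pmax(v, 1e-12))
}

#' Run the full cross-validated group-decision pipeline
#'
#' End-to-end evaluation harness: per outer fold, CSP transformations
#' and confidence models are fitted on that fold's training trials only
#' (no leakage); confidence weights are estimated on the held-out test
#' trials; test-trial predictions are concatenated across folds to cover
#' every trial exactly once; and group decisions are evaluated for every
#' enumerated group under each requested weighting method.
#'
#' Methods: \code{majority} (all weights 1), \code{rtci} (logistic model
#' on response time only), \code{nf_bci} (the two CSP log-variance
#' neural features), \code{hbci} (response time plus both neural
#' features), \code{confidence_majority} (raw reported 0-100 confidence
#' as weight) and \code{second_majority} (standard majority over the
#' second responses, communication cohorts only).
#'
#' @param cohort An \code{hbci_cohort} (preprocessed internally) or a
#'   list of \code{processed_session} objects from
#'   \code{\link{preprocess_session}}.
#' @param methods Character vector of method names (see Details).
#' @param sizes Group sizes to evaluate; defaults to \code{1:n} for
#'   independent cohorts and to even sizes (whole pairs) for
#'   communication cohorts.
#' @param n_folds Outer folds (default 10).
#' @param seed Seed controlling fold assignment, inner CV splits and
#'   tie-break draws.
#' @param enumeration \code{"all_subsets"} or \code{"pair_preserving"};
#'   default follows the cohort type.
#' @param pairs Two-column pair matrix (required for
#'   \code{pair_preserving} when the cohort does not carry one).
#' @param n_taps,lp_order Filter parameters forwarded to preprocessing
#'   (raw cohorts only).
#' @param keep_models Keep per-fold fitted CSP and confidence models in
#'   the result (for audits).
#' @param force_unit_weights Diagnostic: method names whose estimated
#'   weights are replaced by 1 after fitting (a method so forced must
#'   reproduce plain majority given the same seed).
#' @return An object of class \code{hbci_cv_result}: \code{errors}
#'   (data frame: method, size, group, error_rate, n_ties),
#'   \code{individual} (per-participant error rates), \code{weights}
#'   (per-method participants x trials matrices), \code{confidence}
#'   (estimated w per participant x trial, hybrid features),
#'   \code{trials}, \code{folds}, \code{fallbacks}, optionally
#'   \code{models}.
#' @export
run_pipeline_cv <- function(cohort,
                            methods = c("majority", "rtci", "nf_bci",
                                        "hbci", "confidence_majority"),
                            sizes = NULL, n_folds = 10L, seed = 1L,
                            enumeration = NULL, pairs = NULL,
                            n_taps = NULL, lp_order = NULL,
                            keep_models = FALSE,
                            force_unit_weights = character()) {
  known <- c("majority", "rtci", "nf_bci", "hbci", "confidence_majority",
             "second_majority")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))

  if (inherits(cohort, "hbci_cohort")) {
    if (is.null(pairs)) pairs <- attr(cohort, "pairs")
    processed <- lapply(cohort, preprocess_session,
                        n_taps = n_taps, lp_order = lp_order)
  } else {
    processed <- cohort
    stopifnot(all(vapply(processed, inherits, TRUE, "processed_session")))
  }
  n_p <- length(processed)

  # common trial set across participants
  trial_ids <- Reduce(intersect, lapply(processed, function(s) s$trials$trial))
  n_trials <- length(trial_ids)
  beh <- lapply(processed, function(s)
    s$trials[match(trial_ids, s$trials$trial), ])
  truth <- beh[[1]]$stimulus_class  # the correct decision is the true class
  strata <- beh[[1]]$stimulus_class

  D <- do.call(rbind, lapply(beh, function(b) b$decision))
  RT <- do.call(rbind, lapply(beh, function(b) b$rt))
  CORR <- do.call(rbind, lapply(beh, function(b) as.logical(b$correct)))
  CONF <- do.call(rbind, lapply(beh, function(b) b$reported_confidence))
  D2 <- do.call(rbind, lapply(beh, function(b) b$second_decision))

  if ("confidence_majority" %in% methods && anyNA(CONF))
    stop("confidence_majority requires reported confidences for all trials")
  if ("second_majority" %in% methods && anyNA(D2))
    stop("second_majority requires second responses ",
         "(communication cohorts only)")

  folds <- make_folds(n_trials, n_folds, seed = seed, strata = strata)

  model_methods <- intersect(methods, c("rtci", "nf_bci", "hbci"))
  need_nf <- length(intersect(c("nf_bci", "hbci"), methods)) > 0
  W_est <- lapply(model_methods, function(m)
    matrix(NA_real_, n_p, n_trials))
  names(W_est) <- model_methods
  # estimated w from the hybrid features, kept for D_c/D_i contrasts
  W_hybrid <- matrix(NA_real_, n_p, n_trials)
  fallbacks <- list()
  models <- if (keep_models) list() else NULL

  set.seed((seed * 3L + 1L) %% .Machine$integer.max)
  feature_sets <- list(
    rtci = "rt", nf_bci = c("nf_stimulus", "nf_response"),
    hbci = c("nf_stimulus", "nf_response", "rt"))
  fit_methods <- model_methods

  for (p in seq_len(n_p)) {
    sess <- processed[[p]]
    idx <- match(as.character(trial_ids), dimnames(sess$stimulus)[[3]])
    es <- sess$stimulus[, , idx, drop = FALSE]
    er <- sess$response[, , idx, drop = FALSE]
    covs_s <- trial_covariances(es)
    covs_r <- trial_covariances(er)
    flat_s <- matrix(es, nrow = dim(es)[1])
    flat_r <- matrix(er, nrow = dim(er)[1])
    correct_p <- CORR[p, ]

    for (f in folds) {
      nf_s <- nf_r <- NULL
      if (need_nf) {
        csp_s <- tryCatch(fit_csp_from_covs(covs_s[f$train],
                                            correct_p[f$train]),
                          hbci_degenerate_training = function(e) NULL)
        csp_r <- if (is.null(csp_s)) NULL else
          fit_csp_from_covs(covs_r[f$train], correct_p[f$train])
        if (!is.null(csp_s)) {
          nf_s <- logvar_all(flat_s, csp_s$W[1, ])
          nf_r <- logvar_all(flat_r, csp_r$W[1, ])
        }
        if (keep_models)
          models[[sprintf("p%d_f%d_csp", p, f$fold)]] <-
            list(stimulus = csp_s, response = csp_r)
      }
      feats <- cbind(nf_stimulus = nf_s, nf_response = nf_r, rt = RT[p, ])
      if (is.null(colnames(feats)))
        colnames(feats) <- "rt"  # cbind drops names when nf are NULL
      for (m in fit_methods) {
        cols <- feature_sets[[m]]
        if (!all(cols %in% colnames(feats))) {
          # CSP degenerate: neural features unavailable this fold
          w_test <- rep(1, length(f$test))
          fallbacks[[length(fallbacks) + 1L]] <-
            data.frame(participant = p, fold = f$fold, method = m,
                       reason = "degenerate CSP training")
          mod <- constant_confidence_model(1)
        } else {
          X <- feats[, cols, drop = FALSE]
          mod <- tryCatch(
            fit_confidence_model(X[f$train, , drop = FALSE],
                                 correct_p[f$train]),
            hbci_degenerate_training = function(e) {
              fallbacks[[length(fallbacks) + 1L]] <<-
                data.frame(participant = p, fold = f$fold, method = m,
                           reason = "single-class training labels")
              constant_confidence_model(1)
            })
          w_test <- estimate_confidence(mod, X[f$test, , drop = FALSE])
        }
        if (m %in% model_methods) W_est[[m]][p, f$test] <- w_test
        if (m == "hbci") W_hybrid[p, f$test] <- w_test
        if (keep_models)
          models[[sprintf("p%d_f%d_%s", p, f$fold, m)]] <- mod
      }
    }
  }

  # weight matrices per requested method
  weight_for <- function(m) {
    switch(m,
           majority = matrix(1, n_p, n_trials),
           second_majority = matrix(1, n_p, n_trials),
           confidence_majority = CONF,
           W_est[[m]])
  }

  # group enumeration
  if (is.null(enumeration))
    enumeration <- if (is.null(pairs)) "all_subsets" else "pair_preserving"
  enumeration <- match.arg(enumeration,
                           c("all_subsets", "pair_preserving"))
  if (enumeration == "pair_preserving") {
    if (is.null(pairs)) stop("pair_preserving enumeration needs pairs")
    if (is.null(sizes)) sizes <- 2L * seq_len(nrow(pairs))
    if (any(sizes %% 2L != 0L))
      stop("odd-sized groups are not formed under pair_preserving")
    groups_of <- function(m) enumerate_pair_groups(pairs, m %/% 2L)
  } else {
    if (is.null(sizes)) sizes <- seq_len(n_p)
    groups_of <- function(m) enumerate_groups(n_p, m)
  }

  errors <- list()
  for (m in methods) {
    Wm <- weight_for(m)
    if (m %in% force_unit_weights) Wm <- matrix(1, n_p, n_trials)
    Dm <- if (m == "second_majority") D2 else D
    for (s in sizes) {
      grp <- groups_of(s)
      # tie draws depend on (seed, size) only, never on the method, so
      # methods are compared under identical tie-break randomness
      tie_seed <- (abs(seed) * 97L + s) %% 2147483647L
      res <- evaluate_group_method(grp, Dm, Wm, truth, seed = tie_seed)
      res$method <- m
      res$size <- s
      errors[[length(errors) + 1L]] <- res
    }
  }
  errors <- do.call(rbind, errors)[, c("method", "size", "group",
                                       "error_rate", "n_ties")]

  individual <- data.frame(
    participant = seq_len(n_p),
    error_rate = rowMeans(D != matrix(truth, n_p, n_trials, byrow = TRUE)),
    second_error_rate = if (all(is.na(D2))) NA_real_ else
      rowMeans(D2 != matrix(truth, n_p, n_trials, byrow = TRUE))
  )

  structure(
    list(errors = errors, individual = individual,
         weights = c(W_est, list(reported = CONF)),
         confidence = W_hybrid, correct = CORR,
         trials = beh[[1]][, c("trial", "block", "stimulus_class")],
         folds = folds,
         fallbacks = if (length(fallbacks)) do.call(rbind, fallbacks) else
           NULL,
         models = models, methods = methods, seed = seed),
    class = "hbci_cv_result"
  )
}

#' @export
print.hbci_cv_result <- function(x, ...) {
  agg <- stats::aggregate(error_rate ~ method + size, x$errors, mean)
  cat(sprintf("<hbci_cv_result> %d participants, %d trials, methods: %s\n",
              nrow(x$individual), nrow(x$trials),
              paste(x$methods, collapse = ", ")))
  print(utils::head(agg[order(agg$size, agg$method), ], 20), row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two methods' group error rates
#'
#' Wilcoxon signed-rank test on paired per-group error rates (same
#' groups under two methods). One-sided by default, testing whether the
#' first method's errors are smaller. The exact distribution is used for
#' 25 or fewer pairs (falling back to the normal approximation in the
#' presence of ties or zero differences, as is standard); above 25 pairs
#' the normal approximation with continuity correction is used. All-zero
#' differences report no difference (p = 1).
#'
#' @param errors_a,errors_b Paired numeric vectors of per-group error
#'   rates.
#' @param sided \code{"one"} (a less than b) or \code{"two"}.
#' @return List: \code{statistic} (V), \code{p.value}, \code{n},
#'   \code{method}.
#' @export
compare_methods <- function(errors_a, errors_b, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(length(errors_a) == length(errors_b))
  d <- errors_a - errors_b
  n <- length(d)
  if (all(d == 0))
    return(list(statistic = NA_real_, p.value = 1, n = n,
                method = "Wilcoxon signed-rank (no differences)"))
  alt <- if (sided == "one") "less" else "two.sided"
  wt <- suppressWarnings(
    wilcox.test(errors_a, errors_b, paired = TRUE, alternative = alt,
                exact = n <= 25, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
       method = "Wilcoxon signed-rank")
}

#' Kruskal-Wallis contrast of two value sets
#'
#' Compares the distributions of a measure (response times, reported
#' confidence, estimated confidence, per-sample ERP voltage) between the
#' correct set \eqn{D_c} and the incorrect set \eqn{D_i}. With two
#' groups the Kruskal-Wallis statistic is the rank-sum test on ranks;
#' ties are corrected.
#'
#' @param values_c,values_i Numeric vectors (both non-empty).
#' @return List: \code{statistic} (H, tie-corrected), \code{p.value},
#'   \code{n}.
#' @export
distribution_contrast <- function(values_c, values_i) {
  if (length(values_c) == 0L || length(values_i) == 0L)
    stop("both sets must be non-empty")
  x <- c(values_c, values_i)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p.value = 1,
                n = c(length(values_c), length(values_i))))
  g <- rep(c("c", "i"), c(length(values_c), length(values_i)))
  kt <- kruskal.test(x, factor(g))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       n = c(length(values_c), length(values_i)))
}

#' ERP grand averages and per-sample correct/incorrect contrast
#'
#' Computes grand-average waveforms for the correct and incorrect trial
#' sets and a Kruskal-Wallis p-value per channel and time sample, on the
#' common 48-sample (32 Hz) epoch grid. No multiple-testing correction
#' is applied across samples or channels; the conventional 5% level is
#' the reference line.
#'
#' @param epochs_c,epochs_i Channels x 48 x trials arrays with matching
#'   channel sets.
#' @param lock \code{"stimulus"} (time axis 0 to 1.5 s from onset) or
#'   \code{"response"} (-1.0 to 0.5 s around the response).
#' @return List of class \code{erp_contrast}: \code{avg_c}, \code{avg_i}
#'   (channels x 48), \code{p} (channels x 48), \code{channels},
#'   \code{times}, \code{lock}.
#' @export
erp_contrast <- function(epochs_c, epochs_i,
                         lock = c("stimulus", "response")) {
  lock <- match.arg(lock)
  stopifnot(length(dim(epochs_c)) == 3L, length(dim(epochs_i)) == 3L,
            dim(epochs_c)[2] == 48L, dim(epochs_i)[2] == 48L)
  if (dim(epochs_c)[1] != dim(epochs_i)[1] ||
      !identical(dimnames(epochs_c)[[1]], dimnames(epochs_i)[[1]]))
    stop("mismatched channel sets")
  n_ch <- dim(epochs_c)[1]
  avg_c <- apply(epochs_c, c(1, 2), mean)
  avg_i <- apply(epochs_i, c(1, 2), mean)
  p <- matrix(NA_real_, n_ch, 48L,
              dimnames = list(dimnames(epochs_c)[[1]], NULL))
  for (ch in seq_len(n_ch)) for (s in seq_len(48L)) {
    p[ch, s] <- distribution_contrast(epochs_c[ch, s, ],
                                      epochs_i[ch, s, ])$p.value
  }
  times <- if (lock == "stimulus") (0:47) / 32 else (0:47) / 32 - 1.0
  structure(list(avg_c = avg_c, avg_i = avg_i, p = p,
                 channels = dimnames(epochs_c)[[1]], times = times,
                 lock = lock),
            class = "erp_contrast")
}

#' Export scalp-map values at named latencies
#'
#' Pulls, for each requested latency, the per-channel contrast p-value
#' and grand-average difference at the nearest epoch sample — the values
#' needed to render a scalp map (rendering itself is out of scope).
#' Conventional latencies are 0.6 and 0.9 s after stimulus onset and
#' -0.2/+0.2 s around the response.
#'
#' @param contrast An \code{\link{erp_contrast}} result.
#' @param times Latencies in seconds on the contrast's time axis;
#'   defaults to the conventional latencies for its lock type.
#' @return Data frame: channel, time (actual sample time), p,
#'   \code{diff} (correct minus incorrect grand average).
#' @export
erp_scalp_values <- function(contrast, times = NULL) {
  stopifnot(inherits(contrast, "erp_contrast"))
  if (is.null(times))
    times <- if (contrast$lock == "stimulus") c(0.6, 0.9) else c(-0.2, 0.2)
  do.call(rbind, lapply(times, function(t0) {
    s <- which.min(abs(contrast$times - t0))
    data.frame(channel = contrast$channels, time = contrast$times[s],
               p = contrast$p[, s],
               diff = contrast$avg_c[, s] - contrast$avg_i[, s],
               row.names = NULL)
  }))
}

#' Moving-average error dynamics with linear trend
#'
#' Simple moving average of a 0/1 error (or disagreement) indicator over
#' overlapping windows of consecutive trials advancing one trial at a
#' time, plus an ordinary least-squares line fit to the smoothed series
#' with its correlation coefficient and two-sided p-value.
#'
#' @param flags 0/1 (or logical) indicator sequence in trial order.
#' @param window Window length in trials (default 40).
#' @return List: \code{index} (trial index of each window end),
#'   \code{series} (windowed means), \code{slope}, \code{intercept},
#'   \code{r} (Pearson correlation of series with index), \code{p}
#'   (two-sided). For a single window or a constant series \code{r} and
#'   \code{p} are \code{NA}.
#' @export
moving_average_error <- function(flags, window = 40L) {
  flags <- as.numeric(flags)
  n <- length(flags)
  if (window > n) stop("window longer than the series")
  if (window < 1L) stop("window must be at least 1")
  cs <- c(0, cumsum(flags))
  series <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  index <- window:n
  if (length(series) < 2L || sd(series) == 0) {
    fit <- lm(series ~ index)
    return(list(index = index, series = series,
                slope = if (length(series) < 2L) NA_real_ else
                  unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r = NA_real_, p = NA_real_))
  }
  fit <- lm(series ~ index)
  ct <- cor.test(series, index)
  list(index = index, series = series,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value)
}
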
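test_that("fold splits partition trials with the expected sizes", {
  f <- make_folds(320, 10, seed = 1)
  expect_length(f, 10)
  for (fi in f) {
    expect_length(fi$train, 288)
    expect_length(fi$test, 32)
    expect_equal(sort(c(fi$train, fi$test)), 1:320)
  }
  tests <- sort(unlist(lapply(f, `[[`, "test")))
  expect_equal(tests, 1:320)   # every trial tested exactly once

  # stratification keeps the class prevalence in every fold
  strata <- rep(c(1, -1), c(80, 240))
  fs <- make_folds(320, 10, seed = 2, strata = strata)
  for (fi in fs) expect_equal(sum(strata[fi$test] == 1), 8)

  # as many folds as trials -> leave-one-out
  loo <- make_folds(10, 10, seed = 3)
  expect_true(all(vapply(loo, function(x) length(x$test), 0L) == 1L))
  expect_error(make_folds(5, 10), "folds")
})

test_that("signed-rank comparison matches exact enumeration (n <= 8)", {
  set.seed(4)
  for (k in 1:5) {
    n <- sample(5:8, 1)
    a <- runif(n)
    b <- a + rnorm(n, mean = -0.1, sd = 0.3)
    d <- a - b
    if (any(d == 0) || any(duplicated(abs(d)))) next
    r <- compare_methods(a, b, sided = "one")
    expect_equal(r$p.value, wsr_exact_p(d), tolerance = 1e-12)
  }
  # n = 5, all differences negative: the table value is 1/32
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  b <- a + c(0.11, 0.12, 0.13, 0.14, 0.15)
  expect_equal(compare_methods(a, b, sided = "one")$p.value, 1 / 32)
  # identical vectors report no difference
  expect_equal(compare_methods(a, a)$p.value, 1)
})

test_that("Kruskal-Wallis contrast matches a hand rank computation with ties", {
  # 6-point tied-heavy example, tie-corrected H computed from first
  # principles
  x <- c(1, 2, 2, 3)
  y <- c(2, 3)
  res <- distribution_contrast(x, y)
  expect_equal(res$statistic, kw_hand_h(x, y), tolerance = 1e-12)

  # identical samples: no separation
  same <- distribution_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1, tolerance = 1e-9)
  # well-separated normals: overwhelming evidence
  set.seed(5)
  far <- distribution_contrast(rnorm(100), rnorm(100, mean = 3))
  expect_lt(far$p.value, 1e-10)
  expect_error(distribution_contrast(numeric(0), 1), "non-empty")
})

test_that("ERP contrasts compute grand averages and per-sample p-values", {
  set.seed(6)
  ec <- array(rnorm(3 * 48 * 30), c(3, 48, 30),
              dimnames = list(c("Cz", "Pz", "POz"), NULL, NULL))
  # identical sets: identical averages, all p ~ 1
  same <- erp_contrast(ec, ec)
  expect_equal(same$avg_c, same$avg_i)
  expect_true(all(same$p > 0.99))
  # constant epochs: the grand average is the constant
  const <- array(7, c(3, 48, 10), dimnames = list(c("Cz", "Pz", "POz"),
                                                  NULL, NULL))
  cc <- erp_contrast(const, const + 0)
  expect_true(all(cc$avg_c == 7))
  # an injected difference at known samples is detected there
  ei <- ec[, , 1:30]
  ei[1, 20:24, ] <- ei[1, 20:24, ] + 2.5
  dif <- erp_contrast(ec, ei)
  expect_true(all(dif$p[1, 21:23] < 0.01))
  expect_gt(mean(dif$p[2, ] > 0.05), 0.8)
  # time axes follow the lock type
  expect_equal(erp_contrast(ec, ei, lock = "stimulus")$times[1], 0)
  expect_equal(erp_contrast(ec, ei, lock = "response")$times[1], -1)
  expect_error(erp_contrast(ec, ec[1:2, , ]), "channel")

  sc <- erp_scalp_values(dif, times = 21 / 32)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$p, unname(dif$p[, 22]))
})

test_that("moving-average error dynamics and trend fit behave as defined", {
  # constant indicator: flat series, zero slope
  r <- moving_average_error(rep(1, 100), window = 40)
  expect_true(all(r$series == 1))
  expect_equal(r$slope, 0)
  # window = length: single point equal to the overall mean
  r1 <- moving_average_error(c(0, 1, 1, 0), window = 4)
  expect_equal(r1$series, 0.5)
  expect_true(is.na(r1$slope))
  # alternating series, window 2: all values 0.5
  r2 <- moving_average_error(rep(c(0, 1), 25), window = 2)
  expect_true(all(r2$series == 0.5))
  # a genuinely improving observer yields a negative fitted slope
  set.seed(7)
  p_err <- seq(0.45, 0.1, length.out = 320)
  flags <- runif(320) < p_err
  r3 <- moving_average_error(flags, window = 40)
  expect_lt(r3$slope, 0)
  expect_lt(r3$p, 0.01)
  expect_error(moving_average_error(c(0, 1), window = 3), "window")
})

test_that("declining individual errors shrink the tie rate of off-line pairs", {
  # two independent improving observers: disagreement (tie) rate declines
  set.seed(8)
  p_err <- seq(0.45, 0.08, length.out = 320)
  d1 <- ifelse(runif(320) < p_err, -1, 1)
  d2 <- ifelse(runif(320) < p_err, -1, 1)
  tie <- d1 != d2
  r <- moving_average_error(tie, window = 40)
  expect_lt(r$slope, 0)
  expect_lt(r$p, 0.05)
})

test_that("the cross-validated pipeline covers trials once and reduces to majority", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg)
  pp <- lapply(coh, preprocess_session)
  res <- run_pipeline_cv(pp, methods = c("majority", "hbci"),
                         sizes = c(1, 2), n_folds = 5, seed = 31)
  # every trial receives exactly one test-fold prediction
  expect_true(all(is.finite(res$confidence)))
  tests <- sort(unlist(lapply(res$folds, `[[`, "test")))
  expect_equal(tests, seq_len(nrow(res$trials)))
  # size-1 groups reproduce individual error rates
  solo <- subset(res$errors, method == "majority" & size == 1)
  expect_equal(solo$error_rate, res$individual$error_rate)
  # hbci with unit-forced weights equals majority under the same tie seed
  res_f <- run_pipeline_cv(pp, methods = c("majority", "hbci"),
                           sizes = c(1, 2), n_folds = 5, seed = 31,
                           force_unit_weights = "hbci")
  a <- subset(res_f$errors, method == "hbci")
  b <- subset(res_f$errors, method == "majority")
  expect_equal(a$error_rate, b$error_rate)
  expect_equal(a$n_ties, b$n_ties)
})

test_that("test-trial perturbations never leak into fitted models", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg)
  pp <- lapply(coh, preprocess_session)
  res <- run_pipeline_cv(pp, methods = "hbci", sizes = 1, n_folds = 5,
                         seed = 41, keep_models = TRUE)
  f1_test <- res$folds[[1]]$test
  pp2 <- pp
  pp2[[1]]$stimulus[, , f1_test[1]] <-
    pp2[[1]]$stimulus[, , f1_test[1]] + 50
  pp2[[1]]$trials$rt[f1_test[1]] <- 9 # behavioural features too
  res2 <- run_pipeline_cv(pp2, methods = "hbci", sizes = 1, n_folds = 5,
                          seed = 41, keep_models = TRUE)
  m1 <- res$models[["p1_f1_hbci"]]
  m2 <- res2$models[["p1_f1_hbci"]]
  expect_equal(m1$coef, m2$coef, tolerance = 1e-10)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-10)
  expect_equal(m1$C, m2$C)
  c1 <- res$models[["p1_f1_csp"]]
  c2 <- res2$models[["p1_f1_csp"]]
  expect_equal(c1$stimulus$W, c2$stimulus$W, tolerance = 1e-10)
})

test_that("pair-preserving evaluation forms only whole-pair groups", {
  cfg <- sim_config(n_participants = 4, n_blocks = 2, trials_per_block = 12,
                    sampling_rate = 128, n_channels = 8,
                    communication_mode = TRUE, error_rate = 0.3, seed = 51)
  coh <- simulate_cohort(cfg)
  res <- run_pipeline_cv(coh, methods = c("majority", "second_majority"),
                         n_folds = 5, seed = 51)
  expect_equal(sort(unique(res$errors$size)), c(2L, 4L))
  expect_equal(sum(res$errors$method == "majority" &
                     res$errors$size == 2), 2L)  # the 2 pairs
  expect_false(anyNA(res$individual$second_error_rate))
  expect_error(run_pipeline_cv(coh, methods = "majority", sizes = 3,
                               n_folds = 5, seed = 51), "odd")
})
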
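test_that("stay tables count scripted repeats exactly", {
  # 6 scripted trials -> 5 pairs with known cells
  s <- scripted_session(a1 = c("x", "x", "y", "y", "y", "x"),
                        s2 = c("B", "B", "C", "C", "B", "B"),
                        a2 = c("x", "x", "x", "x", "y", "x"),
                        outcome_level = c(3, 3, 1, 2, 2, 3),
                        reward = c(1, 1, 0, 0.3, 0.3, 1))
  st <- stay_table(s)
  # pairs: (3,common,stay) (3,common,switch) (1,common,stay) (2,common,switch->x? y->y? )
  # trial4 a1=y -> trial5 y: stay after (2, common); trial5 y (s2=B rare) -> trial6 x: switch after (2, rare)
  expect_equal(st$mean["high", "common"], 0.5)
  expect_equal(st$mean["low", "common"], 1)
  expect_equal(st$mean["medium", "common"], 1)
  expect_equal(st$mean["medium", "rare"], 0)
  expect_true(is.na(st$mean["high", "rare"]))
  expect_equal(sum(st$per_session$n), 5)
})

test_that("an always-repeating agent has unit stay probability", {
  cfg <- task_config(forced_rate = 0)
  sch <- sample_outcome_schedule(cfg, 300, seed = 60)
  sticky <- agent(model_registry()$SARSA,
                  c(alpha1 = 0, alpha2 = 0, beta1 = 100, beta2 = 0,
                    kappa1 = 10, kappa2 = 0, lambda = 0))
  s <- run_session(sticky, cfg, sch, seed = 61)
  st <- stay_table(s)
  expect_true(all(st$mean == 1, na.rm = TRUE))
})

test_that("pure model-sensitive play shows the transition-dependent crossover", {
  ds <- quick_dataset("Forward1", n_sessions = 6, n_trials = 400, seed = 62)
  st <- stay_table(ds)
  expect_gt(st$mean["high", "common"], st$mean["high", "rare"])
  expect_lt(st$mean["low", "common"], st$mean["low", "rare"])
})

test_that("choice design centres, scales and counts columns as specified", {
  # equally frequent outcome levels scale to +/- 1/(2 SD) ~ 0.6124
  lev <- rep(1:3, 700)
  n <- length(lev)
  a1 <- rep(c("x", "y"), length.out = n)
  s <- scripted_session(a1 = a1,
                        s2 = ifelse(a1 == "x", "B", "C"),  # all common
                        a2 = rep("x", n),
                        outcome_level = lev, reward = (lev - 1) / 2)
  d <- build_choice_design(s, n_lags = 5)
  vals <- sort(unique(round(d$R_lag1, 4)))
  expect_equal(vals, c(-0.6124, 0, 0.6124), tolerance = 1e-3)
  expect_equal(ncol(d) - 2, 35)       # 7 terms x 5 lags (+ const in the fit)
  expect_equal(nrow(d), n - 5)
  # all-common sessions make T degenerate and flagged
  expect_true("T_lag1" %in% attr(d, "degenerate"))
  # a 10-trial toy session leaves 5 usable rows
  s10 <- scripted_session(a1 = rep("x", 10), s2 = rep(c("B", "C"), 5),
                          a2 = rep("x", 10), outcome_level = rep(2, 10),
                          reward = rep(0.5, 10))
  expect_equal(nrow(build_choice_design(s10)), 5)
})

test_that("logistic regression recovers known generating weights", {
  set.seed(63)
  n <- 5000
  lev <- sample(1:3, n, replace = TRUE)
  s <- scripted_session(a1 = sample(c("x", "y"), n, TRUE),
                        s2 = sample(c("B", "C"), n, TRUE),
                        a2 = sample(c("x", "y"), n, TRUE),
                        outcome_level = lev,
                        reward = (lev - 1) / 2)
  d <- build_choice_design(s, n_lags = 2)
  truth <- c(`(Intercept)` = 0.2, R_lag1 = 1.2, RxT_lag1 = -0.8)
  eta <- truth[1] + truth[2] * d$R_lag1 + truth[3] * d$RxT_lag1
  d$y <- rbinom(nrow(d), 1, plogis(eta))
  fx <- fit_logistic_fixed(d)
  for (tm in names(truth)) {
    est <- fx$coefficients[1, tm]
    se <- fx$se[1, tm]
    expect_lt(abs(est - truth[tm]), 2 * se)
  }
  # null predictors keep their confidence intervals around zero
  null_terms <- setdiff(fx$summary$term, names(truth))
  covered <- abs(fx$coefficients[1, null_terms] /
                   fx$se[1, null_terms]) < 2.6
  expect_gt(mean(covered, na.rm = TRUE), 0.85)
})

test_that("RT preprocessing z-scores within side and removes outliers", {
  ds <- quick_dataset("Hybrid", 1, 400, seed = 64)
  ds <- simulate_toy_rts(ds, seed = 65)
  s <- ds[[1]]
  ord_before <- order(s$rt1[s$side1 == "left"])
  s$rt1[10] <- s$rt1[10] * 10    # inject a gross outlier
  out <- preprocess_rt(s, "rt1")
  expect_true(is.na(out$rt1_z[10]))
  for (g in c("left", "right", "down")) {
    z <- out$rt1_z[out$side1 == g]
    expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 0.1)
  }
  # monotone within a side
  keep <- out$side1 == "left" & !is.na(out$rt1_z) & seq_len(nrow(out)) != 10
  expect_equal(order(out$rt1_z[out$side1 == "left"][!is.na(
    out$rt1_z[out$side1 == "left"])]),
    order(s$rt1[out$side1 == "left"][!is.na(out$rt1_z[out$side1 == "left"])]))
  expect_error(preprocess_rt(within(s, rt1 <- -rt1), "rt1"), "positive")
})

test_that("RT design has the fatigue column and recovers a lag-1 slope", {
  ds <- quick_dataset("Hybrid", 1, 600, seed = 66)
  ds <- simulate_toy_rts(ds, beta_prev_reward = -0.15, seed = 67)
  ds <- preprocess_rt(ds, "rt1")
  d <- build_rt_design(ds, n_lags = 5)
  expect_equal(ncol(d) - 2, 16)   # fatigue + 3 x 5 lags (+ const in the fit)
  # fatigue is the scaled trial index: near-centred (burn-in rows dropped
  # after centering), monotone increasing
  expect_lt(abs(mean(d$fatigue)), 0.05)
  expect_true(all(diff(d$fatigue) > 0))
  fx <- fit_linear_fixed(d)
  expect_lt(fx$coefficients[1, "R_lag1"] + 2 * fx$se[1, "R_lag1"], 0)
})

test_that("exponential decay fits are exact on exact input and stable on noise", {
  lags <- 1:5
  y <- 2.4 * exp(-0.78 * lags)
  f <- fit_decay(y)
  expect_equal(f$b, -0.78, tolerance = 1e-6)
  expect_equal(f$A, 2.4, tolerance = 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  # idempotence: refitting the fitted values reproduces (A, b)
  f2 <- fit_decay(f$fitted)
  expect_equal(c(f2$A, f2$b), c(f$A, f$b), tolerance = 1e-6)
  # constant input has no decay
  expect_equal(fit_decay(rep(0.7, 5))$b, 0)
  # noisy exponential: the least-squares fit beats the generating parameters
  # on the realized data and stays in the truth's neighbourhood
  set.seed(68)
  yn <- y + rnorm(5, 0, 0.1 * 2.4)
  fn <- fit_decay(yn)
  expect_lte(sum((yn - fn$fitted)^2), sum((yn - y)^2))
  expect_lt(abs(fn$b - (-0.78)), 0.5)
  # sign-alternating input returns a (poor) fit, not an error
  f3 <- fit_decay(c(1, -1, 1, -1, 1))
  expect_lt(f3$adj_r2, 0.5)
})

test_that("coefficient contrasts compare magnitudes across sessions", {
  ds <- quick_dataset("Forward1", 10, 400, seed = 69)
  fx <- fit_logistic_fixed(build_choice_design(ds))
  ct <- coef_contrast(fx, "RxTxC_lag1", "RxC_lag1")
  expect_gt(ct$mean_diff, 0)   # MS play: interaction outweighs reward effect
  expect_lt(ct$p_value, 0.05)
})

test_that("mixed-effects pooling matches the no-heterogeneity limit and shrinks", {
  set.seed(70)
  # several sessions sharing one truth: pooled estimate ~ fixed-effects mean
  parts <- lapply(1:6, function(i) {
    x <- rnorm(300)
    data.frame(session_id = i, y = rbinom(300, 1, plogis(0.8 * x)), x = x)
  })
  d <- do.call(rbind, parts)
  mx <- fit_mixed_regression(d, "logistic")
  fxm <- mean(mx$fixed$coefficients[, "x"])
  i <- match("x", mx$summary$term)
  expect_equal(mx$summary$estimate[i], fxm, tolerance = 0.1)
  expect_lt(mx$summary$p[i], 1e-4)
  # heterogeneous truths: pooled estimate lies inside the session range
  parts2 <- lapply(1:6, function(i) {
    b <- c(-1, -0.5, 0, 0.5, 1, 1.5)[i]
    x <- rnorm(300)
    data.frame(session_id = i, y = rbinom(300, 1, plogis(b * x)), x = x)
  })
  d2 <- do.call(rbind, parts2)
  mx2 <- fit_mixed_regression(d2, "logistic")
  per <- mx2$fixed$coefficients[, "x"]
  est <- mx2$summary$estimate[match("x", mx2$summary$term)]
  expect_gt(est, min(per)); expect_lt(est, max(per))
  expect_gt(mx2$summary$tau2[match("x", mx2$summary$term)], 0)
  # a null predictor is not called significant
  d$z <- rnorm(nrow(d))
  mx3 <- fit_mixed_regression(d, "logistic")
  expect_gt(mx3$summary$p[match("z", mx3$summary$term)], 0.05)
  expect_gt(wald_test(mx3, "z")$p_value, 0.05)
})
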
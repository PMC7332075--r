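hybrid_full <- function(...) {
  spec <- model_spec("SARSA", "Forward1", hybrid_plus = TRUE)
  vals <- list(...)
  base <- c(alpha1 = 0.5, alpha2 = 0.5, beta1 = 1, beta2 = 1, kappa1 = 0,
            kappa2 = 0, lambda = 0, omega = 0.5, L1 = 0, L2 = 0, L3 = 0)
  base[names(vals)] <- unlist(vals)
  spec_full_params(spec, base)
}

test_that("prediction errors match hand evaluation at both stages", {
  st <- init_agent_state()
  st$Q["B", "x"] <- 0.4
  rec <- list(a1 = "x", s2 = "B", a2 = "x", reward = 1.0)
  expect_equal(prediction_error("SARSA", 2, rec, st), 0.6)
  expect_equal(prediction_error("Q", 2, rec, st), 0.6)

  st <- init_agent_state()
  st$Q["B", ] <- c(0.8, 0.9)   # chosen x = 0.8, unchosen y = 0.9
  st$Q["A", "x"] <- 0.2
  rec <- list(a1 = "x", s2 = "B", a2 = "x", reward = 0)
  expect_equal(prediction_error("SARSA", 1, rec, st), 0.6)
  expect_equal(prediction_error("Q", 1, rec, st), 0.7)

  # self-consistency: equal values give zero SARSA error
  st$Q["A", "x"] <- st$Q["B", "x"]
  expect_equal(prediction_error("SARSA", 1, rec, st), 0)
})

test_that("model-free updates follow the learning-rate arithmetic", {
  st <- init_agent_state()
  st$Q["B", "x"] <- 0.5
  rec <- list(a1 = "x", s2 = "B", a2 = "x")
  out <- mf_update(st, rec, delta1 = 0, delta2 = 0.5,
                   hybrid_full(alpha1 = 0, alpha2 = 0.8))
  expect_equal(out$Q["B", "x"], 0.9)

  # zero learning rates leave the state unchanged
  out0 <- mf_update(st, rec, 0.3, 0.5, hybrid_full(alpha1 = 0, alpha2 = 0))
  expect_equal(out0$Q, st$Q)

  # eligibility pass-through: Q(s1,a1) += alpha1 * lambda * delta2
  st <- init_agent_state()
  st$Q["A", "x"] <- 0.2
  out <- mf_update(st, rec, delta1 = 0, delta2 = 0.4,
                   hybrid_full(alpha1 = 0.5, alpha2 = 0, lambda = 0.5))
  expect_equal(out$Q["A", "x"], 0.3)
})

test_that("transition models update their beliefs as specified", {
  st <- init_agent_state()
  # Forward1 ignores any history
  for (i in 1:5) st <- update_transition_model("Forward1", st, "x", "C")
  expect_equal(transition_beliefs(st, "Forward1"), c(x = 0.7, y = 0.3))

  # Forward2 assigns 0.7 to the majority mapping; ties give 0.5
  st <- init_agent_state()
  st$n_map1 <- 7; st$n_map2 <- 3
  expect_equal(transition_beliefs(st, "Forward2"), c(x = 0.7, y = 0.3))
  st$n_map2 <- 7
  expect_equal(transition_beliefs(st, "Forward2"), c(x = 0.5, y = 0.5))

  # Forward3 moves monotonically from near-uniform toward structure
  st <- init_agent_state()
  b0 <- transition_beliefs(st, "Forward3", zeta = 0.5)[["x"]]
  st$n_map1 <- 20; st$n_map2 <- 6
  b1 <- transition_beliefs(st, "Forward3", zeta = 0.5)[["x"]]
  expect_equal(b0, 0.5)
  expect_gt(b1, 0.6)
  expect_lte(b1, 0.7)
})

test_that("model-sensitive values weight second-stage maxima by beliefs", {
  st <- init_agent_state()
  st$Q["B", ] <- c(1, 0.2)
  st$Q["C", ] <- c(0, 0)
  v <- ms_first_stage_values(st, "Forward1")
  expect_equal(v[["x"]], 0.7)
  expect_equal(v[["y"]], 0.3)
  # equal second-stage maxima make values transition-independent
  st$Q["C", ] <- c(1, 0.3)
  v <- ms_first_stage_values(st, "Forward1")
  expect_equal(unname(v), c(1, 1))
})

test_that("hybrid combination respects its limits and arithmetic", {
  q_mf <- c(x = 0.5, y = 0.1); q_ms <- c(x = 1.0, y = 0.4)
  expect_equal(combine_hybrid(q_mf, q_ms, 0), q_mf)
  expect_equal(combine_hybrid(q_mf, q_ms, 1), q_ms)
  expect_equal(combine_hybrid(q_mf, q_ms, 0.86)[["x"]], 0.93)
  expect_error(combine_hybrid(q_mf, q_ms, 1.2), "omega")
})

test_that("the one-trial boost is signed by transition and scaled by level", {
  p <- hybrid_full(L1 = 0.25, L2 = -0.06, L3 = -0.08)
  q <- c(x = 0.5, y = 0.5)
  after_common <- hybridplus_bonus(q, list(a1 = "x", transition = "common",
                                           outcome_level = 3), p)
  expect_equal(after_common[["x"]], 0.75)
  after_rare <- hybridplus_bonus(q, list(a1 = "x", transition = "rare",
                                         outcome_level = 3), p)
  expect_equal(after_rare[["x"]], 0.25)
  # L = 0 collapses to plain Hybrid; no previous trial is a no-op
  p0 <- hybrid_full()
  expect_equal(hybridplus_bonus(q, list(a1 = "x", transition = "rare",
                                        outcome_level = 2), p0), q)
  expect_equal(hybridplus_bonus(q, NULL, p), q)
})

test_that("softmax choice rule matches direct evaluation", {
  expect_equal(choice_probabilities(c(1, 0), beta = 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(1, 0), beta = 1),
               c(0.7311, 0.2689), tolerance = 1e-4)
  p <- choice_probabilities(c(0.5, 0.5), beta = 2, kappa = 0.3,
                            rep = c(1, 0))
  expect_equal(p[1], plogis(2 * 0.3), tolerance = 1e-10)
  expect_equal(sum(p), 1)
  # log-sum-exp guard: extreme values stay finite
  expect_equal(choice_probabilities(c(500, -500), beta = 10), c(1, 0))
  expect_error(choice_probabilities(c(NaN, 0), 1), "non-finite")
})

test_that("the trial pipeline reproduces a hand-rolled SARSA loop", {
  # 5-trial script evaluated by an independent loop written from the update
  # equations, kept free of any package code
  s <- scripted_session(a1 = c("x", "x", "y", "x", "y"),
                        s2 = c("B", "C", "C", "B", "C"),
                        a2 = c("x", "y", "x", "x", "y"),
                        outcome_level = c(3, 1, 2, 3, 2),
                        reward = c(1, 0, 0.3, 0.9, 0.25))
  alpha <- 0.6; beta <- 2; kappa <- 0.2; lambda <- 0.4
  Q <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  last <- c(A = NA, B = NA, C = NA)
  expected <- numeric(0)
  for (t in 1:5) {
    a1 <- s$a1[t]; s2 <- s$s2[t]; a2 <- s$a2[t]; r <- s$reward[t]
    x1 <- beta * (Q["A", ] + kappa * (!is.na(last["A"]) &
                                        colnames(Q) == last["A"]))
    p1 <- exp(x1) / sum(exp(x1))
    x2 <- beta * (Q[s2, ] + kappa * (!is.na(last[s2]) &
                                       colnames(Q) == last[s2]))
    p2 <- exp(x2) / sum(exp(x2))
    expected <- c(expected, log(p1[[a1]]), log(p2[[a2]]))
    d1 <- Q[s2, a2] - Q["A", a1]
    d2 <- r - Q[s2, a2]
    Q["A", a1] <- Q["A", a1] + alpha * d1 + alpha * lambda * d2
    Q[s2, a2] <- Q[s2, a2] + alpha * d2
    last["A"] <- a1; last[s2] <- a2
  }
  spec <- model_registry()$SARSA
  params <- c(alpha1 = alpha, alpha2 = alpha, beta1 = beta, beta2 = beta,
              kappa1 = kappa, kappa2 = kappa, lambda = lambda)
  lp <- reference_session_logp(s, params, spec)
  expect_equal(as.numeric(t(lp)), expected, tolerance = 1e-12)
  expect_equal(session_negloglik(params, s, spec), -sum(expected),
               tolerance = 1e-10)
})

test_that("compiled and reference likelihood paths agree on all variants", {
  models <- list(
    SARSA = preset_params("SARSA", "C"),
    Q = preset_params("SARSA", "C"),
    Forward2 = preset_params("Forward1", "C"),
    Forward3 = c(preset_params("Forward1", "C"), zeta = 0.6),
    Hybrid = preset_params("Hybrid", "C"),
    HybridPlus = preset_params("HybridPlus", "C"))
  cfg <- task_config(error_rate = 0.05)
  set.seed(20)
  for (m in names(models)) {
    spec <- model_registry()[[m]]
    sch <- sample_outcome_schedule(cfg, 250)
    s <- run_session(agent(spec, models[[m]]), cfg, sch)
    lp <- reference_session_logp(s, models[[m]], spec)
    expect_equal(-sum(lp, na.rm = TRUE),
                 session_negloglik(models[[m]], s, spec),
                 tolerance = 1e-9, label = m)
  }
})

test_that("forced stages contribute certainty but still update the learner", {
  s <- scripted_session(a1 = c("x", "x"), s2 = c("B", "B"),
                        a2 = c("x", "y"), outcome_level = c(3, 3),
                        reward = c(1, 1), forced_stage = c(1L, 0L))
  spec <- model_registry()$SARSA
  params <- c(alpha1 = 0.5, alpha2 = 0.5, beta1 = 3, beta2 = 3,
              kappa1 = 1, kappa2 = 0, lambda = 0)
  lp <- reference_session_logp(s, params, spec)
  expect_equal(lp[1, 1], 0)                    # forced first stage
  # trial 2's stage-1 probability reflects perseveration learned on trial 1
  full <- spec_full_params(spec, params)
  st <- agent_trial_step(init_agent_state(), full, spec, as.list(s[1, ]))$state
  expect_equal(st$last_choice[["A"]], "x")
  expect_gt(exp(lp[2, 1]), 0.5)
})

test_that("irrelevant nested parameters do not move the likelihood", {
  # omega = 1 makes lambda inert
  spec <- model_spec("SARSA", "Forward1")
  s <- quick_dataset("Hybrid", n_sessions = 1, n_trials = 150, seed = 21)[[1]]
  base <- c(alpha1 = 0.7, alpha2 = 0.7, beta1 = 4, beta2 = 2,
            kappa1 = 0.1, kappa2 = 0.1, omega = 1)
  nll_a <- session_negloglik(c(base, lambda = 0), s, spec)
  nll_b <- session_negloglik(c(base, lambda = 0.9), s, spec)
  expect_equal(nll_a, nll_b, tolerance = 1e-10)
  # hybrid at omega = 0 / 1 equals the pure systems exactly
  mf <- c(alpha1 = 0.6, alpha2 = 0.75, beta1 = 3, beta2 = 2,
          kappa1 = 0.1, kappa2 = 0.05, lambda = 0.3)
  expect_equal(session_negloglik(c(mf, omega = 0), s, spec),
               session_negloglik(mf, s, model_registry()$SARSA),
               tolerance = 1e-10)
  ms <- c(alpha2 = 0.75, beta1 = 3, beta2 = 2, kappa1 = 0.1)
  expect_equal(
    session_negloglik(c(alpha1 = 0.5, alpha2 = 0.75, beta1 = 3, beta2 = 2,
                        kappa1 = 0.1, kappa2 = 0.1, lambda = 0, omega = 1),
                      s, spec),
    session_negloglik(c(ms, kappa2 = 0.1),
                      s, model_spec("none", "Forward1")),
    tolerance = 1e-10)
})

test_that("values stay bounded for rewards and rates in the unit interval", {
  cfg <- task_config(forced_rate = 0)
  set.seed(22)
  for (rep in 1:3) {
    params <- c(alpha1 = runif(1), alpha2 = runif(1), beta1 = runif(1, 0, 5),
                beta2 = runif(1, 0, 5), kappa1 = 0, kappa2 = 0,
                lambda = runif(1))
    spec <- model_registry()$SARSA
    sch <- sample_outcome_schedule(cfg, 400)
    s <- run_session(agent(spec, params), cfg, sch)
    st <- init_agent_state()
    full <- spec_full_params(spec, params)
    for (t in seq_len(nrow(s))) {
      step <- agent_trial_step(st, full, spec, as.list(s[t, ]))
      st <- step$state
      expect_true(all(st$Q >= 0 & st$Q <= 1))
      expect_true(all(step$p1 > 0 & step$p1 < 1))
      expect_equal(sum(step$p1), 1, tolerance = 1e-12)
      expect_equal(sum(step$p2), 1, tolerance = 1e-12)
    }
  }
})

test_that("inconsistent transition labels are rejected", {
  s <- scripted_session("x", "B", "x", 3, 1)
  s$transition <- "rare"
  full <- spec_full_params(model_registry()$SARSA,
                           preset_params("SARSA", "C"))
  expect_error(agent_trial_step(init_agent_state(), full,
                                model_registry()$SARSA, as.list(s[1, ])),
               "contradicts")
})
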
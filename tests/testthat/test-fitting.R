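test_that("parameter transforms round-trip and unbounded params pass through", {
  spec <- model_registry()$HybridPlus
  tr <- param_transforms(spec)
  x <- c(alpha1 = 0.78, beta1 = 4.57, beta2 = 2.54, kappa1 = 0.06,
         omega = 0.86, L1 = 0.25, L2 = -0.06, L3 = -0.08)
  expect_equal(tr$to_natural(tr$to_unconstrained(x)), x[spec$free],
               tolerance = 1e-10)
  expect_equal(unname(tr$kind[c("kappa1", "L1")]), rep("identity", 2))
  y <- setNames(rnorm(length(spec$free), 0, 2), spec$free)
  expect_equal(tr$to_unconstrained(tr$to_natural(y)), y, tolerance = 1e-8)
})

test_that("a fully random policy yields NLL = 2 T log 2", {
  s <- quick_dataset("SARSA", n_sessions = 1, n_trials = 120, seed = 30)[[1]]
  params <- c(alpha1 = 0.5, alpha2 = 0.5, beta1 = 0, beta2 = 0,
              kappa1 = 0, kappa2 = 0, lambda = 0)
  free1 <- sum(s$forced_stage != 1 & s$error_code == "none")
  free2 <- sum(s$forced_stage != 2 & s$error_code == "none")
  expect_equal(session_negloglik(params, s, model_registry()$SARSA),
               (free1 + free2) * log(2), tolerance = 1e-10)
})

test_that("a session simulated from the fitted params is predicted above chance", {
  s <- quick_dataset("Hybrid", n_sessions = 1, n_trials = 2000, seed = 31,
                     sigma_t = 1e-6)[[1]]
  nll <- session_negloglik(preset_params("Hybrid", "C"), s,
                           model_registry()$Hybrid)
  expect_gt(exp(-nll / n_free_choices(s)), 0.5)
})

test_that("maximum likelihood recovers generating SARSA parameters", {
  cfg <- task_config(forced_rate = 0)
  sch <- sample_outcome_schedule(cfg, 1000, seed = 32)
  gen <- c(alpha1 = 0.8, alpha2 = 0.8, beta1 = 3, beta2 = 3,
           kappa1 = 0, kappa2 = 0, lambda = 0)
  spec <- model_spec("SARSA", "none",
                     ties = c("alpha1=alpha2", "beta1=beta2", "kappa1=0",
                              "kappa2=0", "lambda=0"))
  s <- run_session(agent(spec, gen), cfg, sch, seed = 33)
  fit <- fit_ml_session(s, spec, n_restarts = 5, seed = 34)
  expect_equal(unname(fit$params["alpha1"]), 0.8, tolerance = 0.1)
  # local optimality: refitting from the optimum cannot increase the NLL
  refit_nll <- session_negloglik(fit$params, s, spec)
  expect_lte(refit_nll, fit$nll + 1e-8)
})

test_that("the hybrid nests the pure model-free fit", {
  s <- quick_dataset("SARSA", n_sessions = 1, n_trials = 300, seed = 35)[[1]]
  mf_spec <- model_registry()$SARSA
  hyb_spec <- model_spec("SARSA", "Forward1")  # adds free omega
  fit_mf <- fit_ml_session(s, mf_spec, n_restarts = 4, seed = 36)
  fit_hyb <- fit_ml_session(s, hyb_spec, n_restarts = 8, seed = 36)
  expect_lte(fit_hyb$nll, fit_mf$nll + 0.05)
})

test_that("the M-step implements the moment-matching arithmetic", {
  fits <- list(list(m = c(omega = 0), S = c(omega = 1)),
               list(m = c(omega = 2), S = c(omega = 1)))
  prior <- em_mstep(fits)
  expect_equal(unname(prior$mu), 1)
  expect_equal(unname(prior$sigma), sqrt(2), tolerance = 1e-12)
  # single session: sigma^2 = posterior variance
  one <- em_mstep(list(list(m = c(omega = 0.3), S = c(omega = 0.04))))
  expect_equal(unname(one$sigma), 0.2, tolerance = 1e-12)
  # degenerate case floors the variance and warns
  expect_warning(
    zero <- em_mstep(list(list(m = c(omega = 1), S = c(omega = 0)),
                          list(m = c(omega = 1), S = c(omega = 0)))),
    "floored")
  expect_true(zero$floored)
})

test_that("E-step limits: flat prior recovers ML, flat likelihood the prior", {
  spec <- model_spec("SARSA", "none",
                     ties = c("alpha1=alpha2", "beta1=beta2", "kappa1=0",
                              "kappa2=0", "lambda=0"))
  s <- quick_dataset("SARSA", 1, 400, seed = 37)[[1]]
  ml <- fit_ml_session(s, spec, n_restarts = 4, seed = 38)
  broad <- list(mu = setNames(c(0, 0), spec$free),
                sigma = setNames(c(50, 50), spec$free))
  ef <- em_estep(list(s), broad, spec, n_restarts = 4, seed = 39,
                 warm_start = matrix(ml$params_t, ncol = 1))
  expect_equal(ef[[1]]$m, ml$params_t, tolerance = 0.05)

  # a session with no analyzable trials carries no choice information: the
  # posterior is the prior, so the MAP sits at mu and the Laplace variance
  # equals sigma^2 (closed-form Gaussian oracle)
  sf <- s
  sf$error_code <- "no-choice"
  prior <- list(mu = setNames(c(0.4, 0.8), spec$free),
                sigma = setNames(c(0.5, 0.3), spec$free))
  ef2 <- em_estep(list(sf), prior, spec, n_restarts = 2, seed = 40)
  expect_equal(ef2[[1]]$m, prior$mu, tolerance = 1e-4)
  expect_equal(unname(ef2[[1]]$S), c(0.25, 0.09), tolerance = 0.02)
  expect_true(ef2[[1]]$hessian_ok)
})

test_that("empirical-Bayes EM recovers the hyperprior on a hybrid cohort", {
  spec <- model_registry()$Hybrid
  mu <- preset_params("Hybrid", "C")
  mu["omega"] <- 0.85
  ds <- quick_dataset("Hybrid", n_sessions = 8, n_trials = 400, seed = 41,
                      sigma_t = 0.25, mu = mu)
  fit <- do.call(fit_empirical_bayes,
                 c(list(sessions = ds, spec = spec, seed = 42),
                   test_fit_args))
  expect_equal(unname(fit$prior$mu_natural["omega"]), 0.85, tolerance = 0.1)
  expect_equal(unname(fit$prior$mu_natural["alpha1"]),
               unname(mu["alpha1"]), tolerance = 0.15)
  expect_true(all(fit$prior$sigma > 0))
  # bounded parameters never leave their ranges after fitting
  maps <- t(sapply(fit$fits, `[[`, "map_params"))
  expect_true(all(maps[, "alpha1"] > 0 & maps[, "alpha1"] < 1))
  expect_true(all(maps[, "omega"] > 0 & maps[, "omega"] < 1))
  expect_true(all(maps[, "beta1"] > 0))
})
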
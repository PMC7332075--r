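#' Define a synthetic subject
#'
#' A subject is a generating model plus a Gaussian hyperprior over its free
#' parameters in transformed space, a session count and a trials-per-session
#' distribution. The defaults mirror the study design this package emulates
#' at desk scale: 10 sessions of on average 500 trials (SD 66), the subject-C
#' task calibration, and the Hybrid+ preset means; full scale (30 sessions of
#' 520 trials) is one argument away.
#'
#' @param model preset name (see [model_registry()]), or a [model_spec()]
#'   passed via `spec`.
#' @param subject reward-window preset for [task_config()] and
#'   [preset_params()].
#' @param n_sessions number of sessions.
#' @param trials_mean,trials_sd trials-per-session distribution (Gaussian,
#'   rounded, floored at 50).
#' @param mu named numeric vector of hyperprior means in natural space;
#'   defaults to [preset_params()].
#' @param sigma_t hyperprior SD in transformed space (scalar or named vector).
#' @param spec optional explicit [model_spec()] overriding `model`.
#' @param config a [task_config()]; defaults to the subject preset.
#' @param seed integer seed; the profile plus seed fully determine the
#'   dataset.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(model = "HybridPlus", subject = c("C", "J"),
                            n_sessions = 10, trials_mean = 500,
                            trials_sd = 66, mu = NULL, sigma_t = 0.2,
                            spec = NULL, config = NULL, seed = 1L) {
  subject <- match.arg(subject)
  if (is.null(spec)) spec <- model_registry()[[model]]
  if (is.null(spec)) stop("unknown model preset: ", model)
  if (is.null(mu)) mu <- preset_params(model, subject)
  missing <- setdiff(spec$free, names(mu))
  if (length(missing))
    stop("hyperprior mean missing for: ", paste(missing, collapse = ", "))
  tr <- param_transforms(spec)
  mu_t <- tr$to_unconstrained(mu[spec$free])
  sigma_t <- if (length(sigma_t) == 1)
    setNames(rep(sigma_t, length(spec$free)), spec$free)
  else sigma_t[spec$free]
  if (any(sigma_t <= 0)) stop("sigma_t must be positive")
  structure(list(spec = spec, subject = subject, n_sessions = n_sessions,
                 trials_mean = trials_mean, trials_sd = trials_sd,
                 mu_t = mu_t, sigma_t = sigma_t,
                 config = config %||% task_config(subject = subject),
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' Generate a full synthetic dataset for one subject
#'
#' Per session: draws the session's parameters from the hyperprior, samples a
#' fresh outcome schedule, and lets the agent play. Fully reproducible from
#' the profile's seed.
#'
#' @param profile a [subject_profile()].
#' @return list of `session_data` frames; the drawn per-session parameters
#'   (natural space) are attached as attribute `"true_params"` (data frame)
#'   and per session as attribute `"params"`.
#' @export
generate_subject_dataset <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  set.seed(profile$seed)
  spec <- profile$spec
  tr <- param_transforms(spec)
  k <- length(spec$free)
  sessions <- vector("list", profile$n_sessions)
  truth <- matrix(NA_real_, profile$n_sessions, k,
                  dimnames = list(NULL, spec$free))
  for (i in seq_len(profile$n_sessions)) {
    n_trials <- max(50L, as.integer(round(
      rnorm(1, profile$trials_mean, profile$trials_sd))))
    h <- setNames(rnorm(k, profile$mu_t, profile$sigma_t), spec$free)
    params <- tr$to_natural(h)
    truth[i, ] <- params
    sched <- sample_outcome_schedule(profile$config, n_trials)
    sessions[[i]] <- run_session(agent(spec, params), profile$config, sched,
                                 session_id = i,
                                 subject_id = profile$subject)
    attr(sessions[[i]], "params") <- params
  }
  attr(sessions, "true_params") <- as.data.frame(truth)
  attr(sessions, "profile") <- profile
  sessions
}

#' Simulate surrogate sessions from fitted parameters
#'
#' For each observed session, replays the agent against that session's exact
#' outcome schedule for `runs` repetitions. Transitions are regenerated under
#' `p_common` (the agent's own first-stage choice determines which transition
#' row applies), while outcome levels and juice magnitudes are replayed
#' exactly; the observed forced-trial sequence (and the forced option, taken
#' from the realized action) and error trials are replayed as-is. Outputs are
#' analyzable by the behavioural statistics exactly like observed data.
#'
#' @param fit an `eb_fit` (each session's MAP parameters are reused across
#'   runs) or a prior list with `mu`/`sigma` in transformed space (parameters
#'   are then redrawn per session and run).
#' @param observed list of `session_data` frames with attached schedules.
#' @param spec required when `fit` is a bare prior.
#' @param runs simulation runs per session.
#' @param seed optional integer seed.
#' @return flat list of simulated `session_data` frames with attributes
#'   `"source_session"` and `"run"`; `session_id` is `"<source>.<run>"`.
#' @export
simulate_from_fit <- function(fit, observed, spec = NULL, runs = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  from_prior <- !inherits(fit, "eb_fit")
  if (!from_prior) spec <- fit$spec
  if (is.null(spec)) stop("spec required when simulating from a bare prior")
  tr <- param_transforms(spec)
  codes <- spec_codes(spec)
  out <- list()
  for (i in seq_along(observed)) {
    obs <- observed[[i]]
    sched <- attr(obs, "schedule")
    if (is.null(sched))
      stop("outcome schedule not reconstructible for session ",
           obs$session_id[1])
    cfg <- sched$config
    n <- nrow(obs)
    forced <- as.integer(obs$forced_stage)
    fopt <- rep(1L, n)
    f1 <- forced == 1 & !is.na(obs$a1)
    f2 <- forced == 2 & !is.na(obs$a2)
    fopt[f1] <- match(obs$a1[f1], c("x", "y"))
    fopt[f2] <- match(obs$a2[f2], c("x", "y"))
    errf <- as.integer(obs$error_code != "none")
    for (r in seq_len(runs)) {
      params <- if (from_prior) {
        tr$to_natural(setNames(rnorm(length(spec$free), fit$mu[spec$free],
                                     fit$sigma[spec$free]), spec$free))
      } else fit$fits[[i]]$map_params
      full <- spec_full_params(spec, params)
      m <- cpp_simulate_session(
        sched$levels[seq_len(n), , drop = FALSE],
        sched$juice_ms[seq_len(n), , drop = FALSE],
        full, codes$mf, codes$ms, codes$hplus,
        forced, fopt, errf, cfg$p_common, cfg$reward_windows$high[2])
      sim <- decode_session(m, sched, cfg,
                            session_id = paste0(obs$session_id[1], ".", r),
                            subject_id = attr(obs, "subject_id") %||% "sim")
      attr(sim, "source_session") <- obs$session_id[1]
      attr(sim, "run") <- r
      out[[length(out) + 1]] <- sim
    }
  }
  out
}

#' Parameter-recovery experiment
#'
#' For each setting in a grid of generating hyperprior means: generate a
#' synthetic subject, fit it hierarchically, and tabulate true versus
#' recovered per-session parameters (MAP estimates) and hyperparameters.
#'
#' @param spec a [model_spec()].
#' @param grid list of named numeric vectors (natural-space hyperprior means
#'   over the spec's free parameters).
#' @param n_sessions,n_trials synthetic subject size per setting.
#' @param sigma_t generating hyperprior SD (transformed space).
#' @param subject task calibration preset.
#' @param seed integer seed.
#' @param fit_args list of overrides passed to [fit_empirical_bayes()]
#'   (e.g. `n_restarts_e`).
#' @return object of class `recovery_report`: `per_session` (long data frame
#'   of true/recovered values), `summary` (bias, RMSE and Spearman rank
#'   correlation per parameter, pooled over the grid), and `hyper`
#'   (generating versus recovered prior means).
#' @export
parameter_recovery <- function(spec, grid, n_sessions = 10, n_trials = 500,
                               sigma_t = 0.2, subject = "C", seed = 1L,
                               fit_args = list()) {
  if (!length(grid)) stop("grid must be non-empty")
  rows <- list(); hyper <- list()
  for (gi in seq_along(grid)) {
    prof <- subject_profile(spec = spec, subject = subject,
                            n_sessions = n_sessions,
                            trials_mean = n_trials, trials_sd = 0,
                            mu = grid[[gi]], sigma_t = sigma_t,
                            seed = seed + gi - 1L)
    ds <- generate_subject_dataset(prof)
    truth <- attr(ds, "true_params")
    fit <- tryCatch(
      do.call(fit_empirical_bayes,
              c(list(sessions = ds, spec = spec, seed = seed + 1000L + gi),
                fit_args)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[gi]] <- data.frame(setting = gi, session = NA, parameter = NA,
                               true = NA, recovered = NA,
                               error = conditionMessage(fit))
      next
    }
    rec <- t(sapply(fit$fits, `[[`, "map_params"))
    for (p in spec$free) {
      rows[[length(rows) + 1]] <- data.frame(
        setting = gi, session = seq_len(n_sessions), parameter = p,
        true = truth[[p]], recovered = rec[, p], error = NA_character_)
    }
    hyper[[gi]] <- data.frame(setting = gi, parameter = spec$free,
                              true_mean = unlist(grid[[gi]])[spec$free],
                              recovered_mean = fit$prior$mu_natural[spec$free])
  }
  per <- do.call(rbind, rows)
  ok <- !is.na(per$parameter)
  summ <- do.call(rbind, lapply(unique(per$parameter[ok]), function(p) {
    d <- per[ok & per$parameter == p, ]
    data.frame(parameter = p,
               bias = mean(d$recovered - d$true),
               rmse = sqrt(mean((d$recovered - d$true)^2)),
               rank_cor = suppressWarnings(
                 cor(d$true, d$recovered, method = "spearman")))
  }))
  structure(list(per_session = per, summary = summ,
                 hyper = do.call(rbind, hyper)),
            class = "recovery_report")
}

#' Model-recovery (confusion) experiment
#'
#' Generates one synthetic subject from each listed model preset, fits every
#' candidate model hierarchically to every dataset, and compares candidates
#' within each dataset by integrated BIC and protected exceedance
#' probability.
#'
#' @param models preset names (see [model_registry()]).
#' @param n_sessions,n_trials synthetic subject size.
#' @param sigma_t generating hyperprior SD (transformed space).
#' @param subject task calibration preset.
#' @param seed integer seed.
#' @param K prior draws for [bic_int()].
#' @param fit_args overrides for [fit_empirical_bayes()].
#' @return list with `bic_int` (generating x fitted matrix), `selected`
#'   (model chosen per generating dataset), `pep` (generating x fitted), and
#'   `diagonal_dominant` (whether every dataset selects its generator).
#' @export
model_recovery <- function(models = c("SARSA", "Forward1", "Hybrid",
                                      "HybridPlus"),
                           n_sessions = 10, n_trials = 500, sigma_t = 0.2,
                           subject = "C", seed = 1L, K = 500,
                           fit_args = list()) {
  reg <- model_registry()
  B <- P <- matrix(NA_real_, length(models), length(models),
                   dimnames = list(generated = models, fitted = models))
  for (g in seq_along(models)) {
    prof <- subject_profile(model = models[g], subject = subject,
                            n_sessions = n_sessions, trials_mean = n_trials,
                            trials_sd = 0, sigma_t = sigma_t,
                            seed = seed + 17L * g)
    ds <- generate_subject_dataset(prof)
    lme <- matrix(NA_real_, length(ds), length(models))
    for (f in seq_along(models)) {
      fit <- do.call(fit_empirical_bayes,
                     c(list(sessions = ds, spec = reg[[models[f]]],
                            seed = seed + 100L * g + f), fit_args))
      bi <- bic_int(ds, fit$prior, reg[[models[f]]], K = K,
                    seed = seed + 200L * g + f)
      B[g, f] <- bi$bic_int
      lme[, f] <- bi$session_lme
    }
    P[g, ] <- protected_exceedance_probability(lme,
                                               seed = seed + 300L * g)$pep
  }
  selected <- models[apply(B, 1, which.min)]
  names(selected) <- models
  list(bic_int = B, selected = selected, pep = P,
       diagonal_dominant = all(selected == models))
}

#' Toy lognormal reaction times for pipeline tests
#'
#' Attaches synthetic first-stage RTs and fixation latencies drawn from a
#' lognormal toy model: a side-specific baseline, an optional linear effect
#' of the previous trial's outcome level on log RT, and Gaussian log-noise.
#' This generator exercises the RT preprocessing/regression pipeline only; it
#' makes no claim of matching any observed RT distribution.
#'
#' @param sessions list of `session_data` frames (or one).
#' @param beta_prev_reward slope of log RT on the previous centred outcome
#'   level.
#' @param sdlog lognormal log-scale SD.
#' @param seed optional integer seed.
#' @return the sessions with `rt1`, `rt2` and `fix_rt` filled in.
#' @export
simulate_toy_rts <- function(sessions, beta_prev_reward = 0, sdlog = 0.2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  single <- inherits(sessions, "session_data")
  sessions <- session_list(sessions)
  side_off <- c(left = 0, right = 0.08, down = -0.05)
  out <- lapply(sessions, function(s) {
    n <- nrow(s)
    prevR <- c(NA, s$outcome_level[-n]) - 2
    prevR[is.na(prevR)] <- 0
    s$rt1 <- exp(log(500) + side_off[s$side1] +
                   beta_prev_reward * prevR + rnorm(n, 0, sdlog))
    s$rt2 <- exp(log(520) + side_off[s$side2] + rnorm(n, 0, sdlog))
    s$fix_rt <- exp(log(300) + beta_prev_reward * prevR + rnorm(n, 0, sdlog))
    s
  })
  if (single) out[[1]] else out
}
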
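# Build a session_data frame from scripted per-trial vectors. Defaults give
# complete free-choice trials; transition is derived from a1/s2.
scripted_session <- function(a1, s2, a2, outcome_level, reward,
                             forced_stage = 0L, error_code = "none",
                             session_id = 1L) {
  n <- length(a1)
  transition <- ifelse((a1 == "x") == (s2 == "B"), "common", "rare")
  transition[is.na(a1)] <- NA
  d <- data.frame(
    session_id = session_id, trial = seq_len(n),
    forced_stage = rep_len(forced_stage, n),
    error_code = rep_len(error_code, n),
    a1 = a1, s2 = s2, transition = transition, a2 = a2,
    outcome_level = outcome_level,
    juice_ms = reward * 900, reward = reward,
    rt1 = NA_real_, rt2 = NA_real_, fix_rt = NA_real_,
    side1 = "left", side2 = "right", stringsAsFactors = FALSE)
  structure(d, max_juice_ms = 900, subject_id = "script",
            class = c("session_data", "data.frame"))
}

# quickly simulate a small dataset from a preset
quick_dataset <- function(model = "Hybrid", n_sessions = 3, n_trials = 200,
                          seed = 1, subject = "C", sigma_t = 0.2, mu = NULL) {
  generate_subject_dataset(subject_profile(
    model = model, subject = subject, n_sessions = n_sessions,
    trials_mean = n_trials, trials_sd = 0, sigma_t = sigma_t, mu = mu,
    seed = seed))
}

# fitting controls used throughout the suite (desk scale)
test_fit_args <- list(n_restarts_ml = 3, n_restarts_e = 3, max_iter = 8)

# evaluate a session's log-likelihood through the exported R reference path
reference_session_logp <- function(session, params, spec) {
  st <- init_agent_state()
  full <- spec_full_params(spec, params)
  lp <- matrix(NA_real_, nrow(session), 2)
  for (t in seq_len(nrow(session))) {
    step <- agent_trial_step(st, full, spec, as.list(session[t, ]))
    lp[t, ] <- c(step$logp1, step$logp2)
    st <- step$state
  }
  lp
}
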
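#' Sample the latent outcome schedule for one session
#'
#' Each of the four second-stage options (states B and C times actions x and
#' y) carries an independent outcome-level process: a level in {1 = low,
#' 2 = medium, 3 = high} is held for a dwell length drawn uniformly from
#' `dwell_min:dwell_max` trials and is then redrawn (staying with probability
#' `p_stay_level`, otherwise switching uniformly to one of the other two
#' levels). A fresh dwell length is drawn at every redraw, including stays.
#' Juice durations follow a Gaussian random walk (SD `drift_sd` per level)
#' clipped to the level's window; the walk restarts uniformly inside the
#' window whenever the level changes. The low level always delivers 0 ms.
#'
#' @param config a [task_config()].
#' @param n_trials number of trials to cover (>= 1).
#' @param seed optional integer; when given, seeds R's RNG locally.
#' @return an object of class `outcome_schedule`: a list with integer matrix
#'   `levels` (`n_trials` x 4), numeric matrix `juice_ms` (`n_trials` x 4),
#'   `redraws` (list of redraw trial indices per option), and the config.
#'   Option columns are ordered (B,x), (B,y), (C,x), (C,y).
#' @export
sample_outcome_schedule <- function(config, n_trials, seed = NULL) {
  validate_task_config(config)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  levels <- matrix(0L, n_trials, 4)
  juice <- matrix(0, n_trials, 4)
  redraws <- vector("list", 4)
  for (opt in 1:4) {
    lev <- sample(3L, 1)
    walk <- draw_in_window(config, lev)
    t <- 1L
    bounds <- integer(0)
    while (t <= n_trials) {
      dwell <- sample(seq.int(config$dwell_min, config$dwell_max), 1)
      seg <- t:min(t + dwell - 1L, n_trials)
      for (s in seg) {
        levels[s, opt] <- lev
        juice[s, opt] <- walk
        walk <- drift_in_window(config, lev, walk)
      }
      t <- t + dwell
      if (t <= n_trials) {
        bounds <- c(bounds, t)
        new_lev <- redraw_level(config, lev)
        if (new_lev != lev) {
          lev <- new_lev
          walk <- draw_in_window(config, lev)
        }
      }
    }
    redraws[[opt]] <- bounds
  }
  structure(list(levels = levels, juice_ms = juice, redraws = redraws,
                 config = config, n_trials = n_trials),
            class = "outcome_schedule")
}

redraw_level <- function(config, lev) {
  if (runif(1) < config$p_stay_level) lev
  else sample(setdiff(1:3, lev), 1)
}

level_name <- function(lev) c("low", "medium", "high")[lev]

draw_in_window <- function(config, lev) {
  w <- config$reward_windows[[level_name(lev)]]
  if (lev == 1L) 0 else runif(1, w[1], w[2])
}

drift_in_window <- function(config, lev, value) {
  if (lev == 1L) return(0)
  w <- config$reward_windows[[level_name(lev)]]
  s <- config$drift_sd[[level_name(lev)]]
  clamp(value + rnorm(1, 0, s), w[1], w[2])
}

#' Draw the second-stage state for a first-stage action
#'
#' The transition mapping is fixed: action `x` commonly leads to state `B`
#' and action `y` to state `C`, each with probability `p_common`; the other
#' state is reached otherwise and the draw is labelled `rare`.
#'
#' @param a1 first-stage action, `"x"` or `"y"`.
#' @param config a [task_config()].
#' @return list with `s2` (`"B"` or `"C"`) and `transition`
#'   (`"common"`/`"rare"`).
#' @export
transition_step <- function(a1, config) {
  if (!a1 %in% c("x", "y")) stop("a1 must be 'x' or 'y'")
  majority <- if (a1 == "x") "B" else "C"
  common <- runif(1) < config$p_common
  list(s2 = if (common) majority else setdiff(c("B", "C"), majority),
       transition = if (common) "common" else "rare")
}

#' Simulate one session of an agent playing the task
#'
#' Composes the transition structure, the outcome schedule and the agent's
#' stochastic choice rule into a full session. Forced trials (rate
#' `config$forced_rate`) present a single option at one stage, chosen
#' uniformly; injected error trials (rate `config$error_rate`) abort without
#' choices or outcome. Rewards seen by the learner during play are juice
#' durations scaled by the maximum deliverable juice; the returned session
#' stores `reward` normalized by the realized session maximum, so the maximum
#' is exactly 1 in any session containing juice.
#'
#' @param agent an [agent()] (a model specification plus parameter values).
#' @param config a [task_config()].
#' @param schedule an [sample_outcome_schedule()] covering `n_trials`.
#' @param n_trials number of trials; defaults to the schedule length.
#' @param session_id,subject_id identifiers stored with the session.
#' @param seed optional integer seed.
#' @return a `session_data` data frame, one row per trial, with the outcome
#'   schedule attached as attribute `"schedule"`.
#' @export
run_session <- function(agent, config, schedule, n_trials = schedule$n_trials,
                        session_id = 1L, subject_id = "sim", seed = NULL) {
  stopifnot(inherits(agent, "rl_agent"), inherits(schedule, "outcome_schedule"))
  if (n_trials > schedule$n_trials)
    stop("schedule does not cover n_trials")
  if (!is.null(seed)) set.seed(seed)
  forced_stage <- ifelse(runif(n_trials) < config$forced_rate,
                         sample(1:2, n_trials, replace = TRUE), 0L)
  forced_opt <- sample(1:2, n_trials, replace = TRUE)
  error_flag <- as.integer(runif(n_trials) < config$error_rate)
  full <- spec_full_params(agent$spec, agent$params)
  codes <- spec_codes(agent$spec)
  m <- cpp_simulate_session(
    schedule$levels[seq_len(n_trials), , drop = FALSE],
    schedule$juice_ms[seq_len(n_trials), , drop = FALSE],
    full, codes$mf, codes$ms, codes$hplus,
    as.integer(forced_stage), as.integer(forced_opt), error_flag,
    config$p_common, config$reward_windows$high[2])
  decode_session(m, schedule, config, session_id, subject_id)
}

decode_session <- function(m, schedule, config, session_id, subject_id) {
  n <- nrow(m)
  err <- m[, 2] == 1
  juice <- m[, 7]
  max_juice <- if (any(!err) && any(juice[!err] > 0, na.rm = TRUE))
    max(juice[!err], na.rm = TRUE) else 0
  sides <- c("left", "right", "down")
  i1 <- pmax(as.integer(m[, 3]), 1L)  # safe indices; error rows masked below
  i2 <- pmax(as.integer(m[, 4]), 1L)
  i3 <- pmax(as.integer(m[, 5]), 1L)
  it <- pmax(as.integer(m[, 8]), 0L) + 1L
  session <- data.frame(
    session_id = session_id,
    trial = seq_len(n),
    forced_stage = as.integer(m[, 1]),
    error_code = ifelse(err, "no-choice", "none"),
    a1 = ifelse(err, NA, c("x", "y")[i1]),
    s2 = ifelse(err, NA, c("B", "C")[i2]),
    transition = ifelse(err, NA, c("rare", "common")[it]),
    a2 = ifelse(err, NA, c("x", "y")[i3]),
    outcome_level = ifelse(err, NA, as.integer(m[, 6])),
    juice_ms = ifelse(err, NA, juice),
    reward = if (max_juice > 0) ifelse(err, NA, juice / max_juice)
             else ifelse(err, NA, 0),
    rt1 = NA_real_, rt2 = NA_real_, fix_rt = NA_real_,
    side1 = sample(sides, n, replace = TRUE),
    side2 = sample(sides, n, replace = TRUE),
    stringsAsFactors = FALSE)
  structure(session, max_juice_ms = max_juice, subject_id = subject_id,
            schedule = schedule, class = c("session_data", "data.frame"))
}

# integer-coded trial matrix consumed by the C++ likelihood
encode_session <- function(session) {
  err <- session$error_code != "none" & !is.na(session$error_code)
  code <- function(x, lv) { i <- match(x, lv); ifelse(is.na(i), 0L, i) }
  cbind(forced_stage = as.integer(session$forced_stage),
        error = as.integer(err),
        a1 = code(session$a1, c("x", "y")),
        s2 = code(session$s2, c("B", "C")),
        a2 = code(session$a2, c("x", "y")),
        level = ifelse(is.na(session$outcome_level), 0L,
                       as.integer(session$outcome_level)),
        reward = ifelse(is.na(session$reward), 0, session$reward),
        transition = ifelse(is.na(session$transition), -1L,
                            as.integer(session$transition == "common")))
}

#' Trials entering behavioural analyses
#'
#' Applies the study's exclusion rules: error trials and (by default) forced
#' trials are removed before any descriptive or regression analysis.
#'
#' @param session a `session_data` data frame.
#' @param drop_forced,drop_errors exclusion toggles.
#' @return the filtered data frame; the number of dropped rows is recorded in
#'   attribute `"n_dropped"`.
#' @export
analyzed_trials <- function(session, drop_forced = TRUE, drop_errors = TRUE) {
  keep <- rep(TRUE, nrow(session))
  if (drop_errors) keep <- keep & (session$error_code == "none")
  if (drop_forced) keep <- keep & (session$forced_stage == 0)
  out <- session[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
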
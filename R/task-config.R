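#' Task configuration for the two-stage decision task
#'
#' Collects the generative parameters of the task environment: the
#' common-transition probability, the dwell-then-redraw dynamics of the
#' outcome levels, the per-level juice-duration windows with Gaussian drift,
#' and the rates of forced and error trials.
#'
#' Outcome levels are coded 1 = low (no juice, long delay), 2 = medium,
#' 3 = high. Juice-duration windows for high and medium must not overlap and
#' the low level always delivers 0 ms of juice. Two reward-window presets are
#' bundled (`subject = "C"` or `"J"`), mirroring the per-animal calibrations
#' of the study design this package emulates.
#'
#' @param p_common probability of the common transition, in (0.5, 1].
#' @param dwell_min,dwell_max bounds (inclusive) of the uniform dwell length,
#'   in trials, for which an outcome level is held before a redraw.
#' @param p_stay_level probability that a redraw keeps the current level; the
#'   remaining mass is split evenly over the other two levels.
#' @param forced_rate fraction of trials on which only a single option is
#'   presented (at the first or second stage, equiprobably).
#' @param error_rate fraction of trials aborted by an injected error (no
#'   choices, no outcome). Simulated agents cannot commit fixation errors, so
#'   the default is 0; the field exists so surrogate data can mimic real
#'   sessions.
#' @param subject reward-window preset, `"C"` or `"J"`; ignored when
#'   `reward_windows` is given explicitly.
#' @param reward_windows named list with elements `high`, `medium`, `low`,
#'   each a length-2 numeric interval of juice durations in ms.
#' @param drift_sd named numeric: SD (ms) of the Gaussian drift applied to
#'   the juice duration at each trial, per level.
#' @param delay_ms named numeric: the fixed extra delay (ms) before delivery
#'   per level. Informational only: delays carry no trial-to-trial
#'   variability and do not enter model fitting.
#'
#' @return an object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$p_common
#' @export
task_config <- function(p_common = 0.7,
                        dwell_min = 5, dwell_max = 9,
                        p_stay_level = 1 / 3,
                        forced_rate = 0.15,
                        error_rate = 0,
                        subject = c("C", "J"),
                        reward_windows = NULL,
                        drift_sd = c(high = 200, medium = 100, low = 0),
                        delay_ms = NULL) {
  subject <- match.arg(subject)
  if (is.null(reward_windows)) {
    reward_windows <- switch(subject,
      C = list(high = c(682, 962), medium = c(117, 390), low = c(0, 0)),
      J = list(high = c(976, 1257), medium = c(507, 826), low = c(0, 0)))
  }
  if (is.null(delay_ms)) {
    delay_ms <- switch(subject,
      C = c(high = 0, medium = 750, low = 2500),
      J = c(high = 0, medium = 1500, low = 4000))
  }
  cfg <- structure(list(
    p_common = p_common, dwell_min = dwell_min, dwell_max = dwell_max,
    p_stay_level = p_stay_level, forced_rate = forced_rate,
    error_rate = error_rate, subject = subject,
    reward_windows = reward_windows, drift_sd = drift_sd,
    delay_ms = delay_ms, n_first_actions = 2L, n_second_actions = 2L),
    class = "task_config")
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(is.numeric(cfg$p_common), length(cfg$p_common) == 1)
  if (cfg$p_common <= 0.5 || cfg$p_common > 1)
    stop("p_common must lie in (0.5, 1]")
  if (cfg$dwell_min > cfg$dwell_max)
    stop("invalid task configuration: dwell_min > dwell_max")
  if (cfg$dwell_min < 1) stop("dwell_min must be >= 1")
  if (cfg$p_stay_level < 0 || cfg$p_stay_level > 1)
    stop("p_stay_level must be a probability")
  if (cfg$forced_rate < 0 || cfg$forced_rate > 1)
    stop("forced_rate must be a probability")
  rw <- cfg$reward_windows
  stopifnot(all(c("high", "medium", "low") %in% names(rw)))
  if (any(rw$low != 0)) stop("low-level juice must be 0")
  overlap <- rw$medium[2] >= rw$high[1] && rw$high[2] >= rw$medium[1]
  if (overlap) stop("high and medium reward windows must not overlap")
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-stage task configuration (subject preset ", x$subject, ")\n",
      sep = "")
  cat("  P(common) =", x$p_common,
      "| dwell", x$dwell_min, "-", x$dwell_max, "trials",
      "| P(stay at redraw) =", round(x$p_stay_level, 3), "\n")
  cat("  forced rate =", x$forced_rate, "| error rate =", x$error_rate, "\n")
  cat("  juice windows (ms): high [",
      paste(x$reward_windows$high, collapse = ", "), "], medium [",
      paste(x$reward_windows$medium, collapse = ", "), "], low 0\n")
  invisible(x)
}
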
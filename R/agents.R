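#' Initialise the learner's state at session start
#'
#' Values start at 0 for every state-action pair, transition-model evidence
#' counts at 0, and no previous-trial summary exists. Nothing is carried over
#' between sessions: parameters and state are per-session quantities.
#'
#' @return an `agent_state` list: `Q` (3 x 2 matrix over states A, B, C and
#'   actions x, y; second-stage rows double as the model-sensitive
#'   second-stage values), transition evidence counts `n_map1`/`n_map2` (for
#'   the mappings x->B,y->C versus x->C,y->B), `last_choice` per state, and
#'   `prev` (previous completed trial's action, transition and outcome level).
#' @export
init_agent_state <- function() {
  structure(list(
    Q = matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y"))),
    n_map1 = 0, n_map2 = 0,
    last_choice = c(A = NA_character_, B = NA_character_, C = NA_character_),
    prev = NULL), class = "agent_state")
}

#' Temporal-difference prediction error
#'
#' At the second stage the successor is a fictitious terminal state of value
#' 0, so both variants give `reward - Q(s2, a2)`. At the first stage the reward is
#' 0 and the variants differ in how they evaluate the second-stage state:
#' SARSA uses the value of the action actually taken, Q-learning the maximum
#' over available actions.
#'
#' @param variant `"SARSA"` or `"Q"`.
#' @param stage 1 or 2.
#' @param record list/row with `a1`, `s2`, `a2`, `reward` as needed.
#' @param state an `agent_state`.
#' @return signed scalar prediction error.
#' @export
prediction_error <- function(variant = c("SARSA", "Q"), stage, record, state) {
  variant <- match.arg(variant)
  if (stage == 2) {
    if (is.na(record$a2)) stop("missing second-stage action on a non-error trial")
    return(record$reward - state$Q[record$s2, record$a2])
  }
  succ <- if (variant == "SARSA") state$Q[record$s2, record$a2]
          else max(state$Q[record$s2, ])
  succ - state$Q["A", record$a1]
}

#' Model-free value update with within-trial eligibility
#'
#' Applies `Q(s1,a1) += alpha1 * delta1`, `Q(s2,a2) += alpha2 * delta2`, and
#' the eligibility pass-through `Q(s1,a1) += alpha1 * lambda * delta2`.
#' Eligibility does not carry across trials.
#'
#' @param state an `agent_state`.
#' @param record trial row with `a1`, `s2`, `a2`.
#' @param delta1,delta2 stage prediction errors.
#' @param params full parameter vector (see [spec_full_params()]).
#' @return the updated state.
#' @export
mf_update <- function(state, record, delta1, delta2, params) {
  state$Q["A", record$a1] <- state$Q["A", record$a1] + params["alpha1"] * delta1
  state$Q[record$s2, record$a2] <-
    state$Q[record$s2, record$a2] + params["alpha2"] * delta2
  state$Q["A", record$a1] <- state$Q["A", record$a1] +
    params["alpha1"] * params["lambda"] * delta2
  state
}

#' Update the transition-structure evidence
#'
#' `Forward1` keeps fixed beliefs; `Forward2` and `Forward3` accumulate
#' counts of the two possible action-state mappings, reset at session start.
#'
#' @inheritParams mf_update
#' @param variant `"Forward1"`, `"Forward2"` or `"Forward3"`.
#' @param a1,s2 the observed first-stage action and second-stage state.
#' @return the updated state.
#' @export
update_transition_model <- function(variant, state, a1, s2) {
  if (variant == "Forward1" || variant == "none") return(state)
  if ((a1 == "x" && s2 == "B") || (a1 == "y" && s2 == "C"))
    state$n_map1 <- state$n_map1 + 1
  else state$n_map2 <- state$n_map2 + 1
  state
}

#' Transition beliefs P(B | a1) under each model-sensitive variant
#'
#' `Forward1`: the true 70/30 structure. `Forward2`: 0.7 assigned to the more
#' frequently observed mapping (0.5/0.5 at ties). `Forward3`: the structured
#' 70/30 account (with the majority mapping) is weighed against a uniform
#' 50/50 account through the likelihood ratio of the observed counts, with
#' prior weight `zeta` on structure; beliefs are the weighted mixture of the
#' two transition matrices.
#'
#' @param state an `agent_state`.
#' @param variant model-sensitive variant name.
#' @param zeta mixing weight in (0, 1) for `Forward3`.
#' @return named vector `c(x = P(B|x), y = P(B|y))`.
#' @export
transition_beliefs <- function(state, variant, zeta = 0.5) {
  if (variant %in% c("Forward1", "none")) return(c(x = 0.7, y = 0.3))
  n1 <- state$n_map1; n2 <- state$n_map2
  if (variant == "Forward2") {
    if (n1 > n2) return(c(x = 0.7, y = 0.3))
    if (n2 > n1) return(c(x = 0.3, y = 0.7))
    return(c(x = 0.5, y = 0.5))
  }
  # Forward3
  logLR <- max(n1, n2) * log(0.7) + min(n1, n2) * log(0.3) -
    (n1 + n2) * log(0.5)
  z <- clamp(zeta, 1e-12, 1 - 1e-12)
  w <- plogis(qlogis(z) + logLR)
  pBx_struct <- if (n1 > n2) 0.7 else if (n2 > n1) 0.3 else 0.5
  c(x = w * pBx_struct + (1 - w) * 0.5,
    y = w * (1 - pBx_struct) + (1 - w) * 0.5)
}

#' Model-sensitive first-stage action values
#'
#' Each first-stage action is valued by the transition-probability-weighted
#' best second-stage value:
#' `Q_MS(A, a) = P(B|a) max_a' Q(B, a') + P(C|a) max_a' Q(C, a')`.
#'
#' @param state an `agent_state`.
#' @param variant model-sensitive variant.
#' @param zeta Forward3 mixing weight.
#' @return named vector of values for actions `x` and `y`.
#' @export
ms_first_stage_values <- function(state, variant = "Forward1", zeta = 0.5) {
  pB <- transition_beliefs(state, variant, zeta)
  maxB <- max(state$Q["B", ]); maxC <- max(state$Q["C", ])
  c(x = pB[["x"]] * maxB + (1 - pB[["x"]]) * maxC,
    y = pB[["y"]] * maxB + (1 - pB[["y"]]) * maxC)
}

#' Hybrid combination of first-stage values
#'
#' @param q_mf,q_ms first-stage value vectors from the two systems.
#' @param omega model-sensitive weight in `[0, 1]`; 0 is pure model-free,
#'   1 pure model-sensitive.
#' @return `(1 - omega) * q_mf + omega * q_ms`.
#' @export
combine_hybrid <- function(q_mf, q_ms, omega) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  (1 - omega) * q_mf + omega * q_ms
}

#' One-trial outcome-dependent boost of the previous first-stage choice
#'
#' The Hybrid+ rule: the action chosen at the first stage of the immediately
#' preceding completed trial receives `+L_j` if that trial's transition was
#' common and `-L_j` if rare, where `j` indexes the previous outcome level
#' (`L1` high, `L2` medium, `L3` low). The boost is recomputed afresh each
#' trial and does not persist or accumulate. With no previous trial the
#' values pass through unchanged.
#'
#' @param q_hyb named first-stage value vector (actions `x`, `y`).
#' @param last `NULL`, or list with `a1`, `transition`
#'   (`"common"`/`"rare"`), and `outcome_level` (1 low .. 3 high).
#' @param params full parameter vector.
#' @param boost_unchosen logical; mirrored variant applying the signed boost
#'   to the unchosen action with opposite sign (off by default).
#' @return the boosted value vector.
#' @export
hybridplus_bonus <- function(q_hyb, last, params, boost_unchosen = FALSE) {
  if (is.null(last)) return(q_hyb)
  L <- switch(as.character(last$outcome_level),
              `3` = params[["L1"]], `2` = params[["L2"]], `1` = params[["L3"]])
  s <- if (last$transition == "common") 1 else -1
  q_hyb[last$a1] <- q_hyb[last$a1] + s * L
  if (boost_unchosen) {
    other <- setdiff(c("x", "y"), last$a1)
    q_hyb[other] <- q_hyb[other] - s * L
  }
  q_hyb
}

#' Softmax choice rule with perseveration
#'
#' Action probabilities are `softmax(beta * (q + kappa * rep))` where `rep`
#' marks the action chosen on the previous visit to the same state. Computed
#' through a log-sum-exp guard, so extreme values do not overflow. `beta = 0`
#' gives fully random choice.
#'
#' @param q value vector.
#' @param beta inverse temperature (>= 0).
#' @param kappa perseveration weight (positive: repeat; negative: switch).
#' @param rep 0/1 indicator vector aligned with `q` (default: no previous
#'   visit).
#' @return probability vector summing to 1.
#' @export
choice_probabilities <- function(q, beta, kappa = 0, rep = NULL) {
  if (is.null(rep)) rep <- numeric(length(q))
  if (beta < 0) stop("beta must be >= 0")
  if (any(!is.finite(q))) stop("non-finite action values")
  x <- beta * (q + kappa * rep)
  e <- exp(x - max(x))
  e / sum(e)
}

rep_indicator <- function(state, s, actions = c("x", "y")) {
  as.numeric(actions == state$last_choice[[s]] &
               !is.na(state$last_choice[[s]]))
}

#' One trial of the agent pipeline (reference implementation)
#'
#' Orders the per-trial computation: Hybrid+ boost of first-stage values,
#' first-stage softmax, transition, second-stage softmax, prediction errors,
#' model-free update, transition-model update, previous-trial summary. The
#' same path serves simulation and likelihood evaluation: given a trial
#' `record` with realized actions it returns the probabilities assigned to
#' them. Forced stages contribute probability 1 while still updating values,
#' perseveration and the trial summary; error trials change nothing.
#'
#' This R implementation is the readable reference for the compiled
#' trial loop used by the fitting routines; the two are tested for equality.
#'
#' @param state an `agent_state`.
#' @param params full parameter vector from [spec_full_params()].
#' @param spec a [model_spec()].
#' @param record one trial row (list or single-row data frame) with fields
#'   `forced_stage`, `error_code`, `a1`, `s2`, `a2`, `outcome_level`,
#'   `reward`, `transition`.
#' @return list with `p1`, `p2` (named probability vectors at each stage),
#'   `logp1`, `logp2` (log-probability of the realized action; 0 at forced
#'   stages, `NA` on error trials) and the updated `state`.
#' @export
agent_trial_step <- function(state, params, spec, record) {
  if (!is.na(record$error_code) && record$error_code != "none")
    return(list(p1 = NULL, p2 = NULL, logp1 = NA_real_, logp2 = NA_real_,
                state = state))
  if (!is.na(record$transition)) {
    expect <- if ((record$a1 == "x") == (record$s2 == "B")) "common" else "rare"
    if (record$transition != expect)
      stop("transition label contradicts a1/s2 on trial record")
  }
  omega <- if (spec$mf == "none") 1 else if (spec$ms == "none") 0
           else params[["omega"]]
  q_mf <- setNames(state$Q["A", ], c("x", "y"))
  q_ms <- ms_first_stage_values(state, spec$ms, params[["zeta"]])
  q1 <- combine_hybrid(q_mf, q_ms, omega)
  if (spec$hybrid_plus) q1 <- hybridplus_bonus(q1, state$prev, params)
  p1 <- choice_probabilities(q1, params[["beta1"]], params[["kappa1"]],
                             rep_indicator(state, "A"))
  names(p1) <- c("x", "y")
  p2 <- choice_probabilities(state$Q[record$s2, ], params[["beta2"]],
                             params[["kappa2"]],
                             rep_indicator(state, record$s2))
  names(p2) <- c("x", "y")
  logp1 <- if (record$forced_stage == 1) 0 else log(p1[[record$a1]])
  logp2 <- if (record$forced_stage == 2) 0 else log(p2[[record$a2]])
  variant <- if (spec$mf == "Q") "Q" else "SARSA"
  d1 <- prediction_error(variant, 1, record, state)
  d2 <- prediction_error(variant, 2, record, state)
  state <- mf_update(state, record, d1, d2, params)
  state <- update_transition_model(spec$ms, state, record$a1, record$s2)
  state$last_choice[["A"]] <- record$a1
  state$last_choice[[record$s2]] <- record$a2
  state$prev <- list(a1 = record$a1, transition = record$transition,
                     outcome_level = record$outcome_level)
  list(p1 = p1, p2 = p2, logp1 = logp1, logp2 = logp2, state = state)
}
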
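#' Bayesian information criterion
#'
#' @param logL maximized log-likelihood.
#' @param k_params number of free parameters.
#' @param n_obs number of observations (>= 1).
#' @return `-2 * logL + k * log(n)`.
#' @export
bic <- function(logL, k_params, n_obs) {
  if (n_obs < 1) stop("n_obs must be >= 1")
  -2 * logL + k_params * log(n_obs)
}

#' Integrated (subject-level) BIC under the empirical prior
#'
#' The subject-level evidence integrates each session's likelihood over the
#' converged empirical prior rather than maximizing it: per session,
#' `log P(A_i)` is estimated as the log of the mean session likelihood over
#' `K` parameter draws from the prior (computed in the log domain via
#' log-sum-exp). Then
#' `BIC_int = -2 * sum_i log P(A_i) + |M| * log|A|`, where `|M|` counts the
#' fitted prior parameters (a mean and a variance per free parameter, so
#' twice the free-parameter count) and `|A|` is the total number of
#' likelihood-contributing trials across sessions.
#'
#' @param sessions list of `session_data` frames.
#' @param prior list with `mu` and `sigma` over the spec's free parameters in
#'   transformed space (e.g. `fit$prior` from [fit_empirical_bayes()]).
#' @param spec a [model_spec()].
#' @param K number of prior draws per session.
#' @param seed optional integer seed.
#' @return list with `bic_int`, `logml` (the summed evidence), `session_lme`
#'   (per-session log marginal evidences), `n_trials`, `n_prior_params`.
#' @export
bic_int <- function(sessions, prior, spec, K = 1000, seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  prior <- align_prior(prior, spec)
  codes <- spec_codes(spec)
  tr <- param_transforms(spec)
  k <- length(spec$free)
  mu <- prior$mu; sg <- prior$sigma
  lme <- vapply(sessions, function(s) {
    enc <- encode_session(s)
    draws <- matrix(rnorm(K * k, rep(mu, each = K), rep(sg, each = K)),
                    nrow = K, dimnames = list(NULL, spec$free))
    ll <- apply(draws, 1, function(h) -nll_encoded(h, enc, spec, codes, tr))
    logsumexp(ll) - log(K)
  }, numeric(1))
  n_trials <- sum(vapply(sessions,
                         function(s) sum(s$error_code == "none"), numeric(1)))
  list(bic_int = -2 * sum(lme) + 2 * k * log(n_trials),
       logml = sum(lme), session_lme = lme,
       n_trials = n_trials, n_prior_params = 2L * k)
}

# variational Dirichlet model of model frequencies (random-effects BMS)
vb_bms <- function(lme, alpha0 = 1, max_iter = 500, tol = 1e-8) {
  N <- nrow(lme); M <- ncol(lme)
  alpha <- rep(alpha0, M)
  g <- matrix(1 / M, N, M)
  for (it in seq_len(max_iter)) {
    lg <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(lg - apply(lg, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  # variational free energy of the frequency model
  Elogr <- digamma(alpha) - digamma(sum(alpha))
  lgn <- ifelse(g > 0, log(g), 0)
  F1 <- sum(g * (lme + rep(Elogr, each = N) - lgn)) +
    lgamma(M * alpha0) - M * lgamma(alpha0) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * Elogr))
  list(alpha = alpha, g = g, F1 = F1)
}

dirichlet_exceedance <- function(alpha, n_samples = 1e5) {
  M <- length(alpha)
  if (M == 2) {
    # r1 ~ Beta(a1, a2); exceedance = P(r1 > 1/2)
    xp1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(c(xp1, 1 - xp1))
  }
  draws <- matrix(rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
                  n_samples, M)
  wins <- max.col(draws, ties.method = "random")
  tabulate(wins, nbins = M) / n_samples
}

#' Protected exceedance probability for random-effects model selection
#'
#' Treats the model identity as a random effect across sessions with a
#' Dirichlet model over model frequencies, estimated by the standard
#' variational scheme. The exceedance probability of each model (probability
#' that its frequency is the largest) is then protected against the null
#' possibility that all models are equally frequent: the posterior
#' probability of that null (the Bayes omnibus risk, from the variational
#' free energy against the equal-frequency evidence) mixes the exceedance
#' probabilities with the uniform 1/M.
#'
#' @param session_log_evidence numeric matrix, sessions x models, of
#'   per-session log model evidences (finite).
#' @param alpha0 symmetric Dirichlet prior count (default 1).
#' @param n_samples Monte-Carlo draws for the exceedance computation when
#'   more than two models are compared.
#' @param seed optional integer seed.
#' @return list with `pep`, `xp` (unprotected), `bor`, `alpha` (posterior
#'   Dirichlet counts), and `expected_freq`.
#' @export
protected_exceedance_probability <- function(session_log_evidence,
                                             alpha0 = 1, n_samples = 1e5,
                                             seed = NULL) {
  lme <- as.matrix(session_log_evidence)
  if (any(!is.finite(lme))) stop("log evidences must be finite")
  M <- ncol(lme)
  if (M == 1) return(list(pep = 1, xp = 1, bor = NA_real_,
                          alpha = alpha0 + nrow(lme), expected_freq = 1))
  if (!is.null(seed)) set.seed(seed)
  fit <- vb_bms(lme, alpha0 = alpha0)
  xp <- dirichlet_exceedance(fit$alpha, n_samples)
  F0 <- sum(apply(lme, 1, logsumexp) - log(M))
  bor <- 1 / (1 + exp(fit$F1 - F0))
  pep <- xp * (1 - bor) + bor / M
  names(pep) <- names(xp) <- colnames(lme)
  list(pep = pep, xp = xp, bor = bor, alpha = fit$alpha,
       expected_freq = fit$alpha / sum(fit$alpha))
}

spec_is_nested <- function(nested, full) {
  comp_ok <- (nested$mf == full$mf || nested$mf == "none") &&
    (nested$ms == full$ms || nested$ms == "none") &&
    !(nested$hybrid_plus && !full$hybrid_plus)
  comp_ok && all(nested$free %in% full$free)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full_fit,nested_fit fit objects carrying `logLik` and `spec`
#'   (e.g. from [fit_ml_session()]), or summed-likelihood equivalents.
#' @param df degrees of freedom; defaults to the difference in free-parameter
#'   counts.
#' @return list with `statistic` (`2 * delta logL`), `df`, `p_value`, and a
#'   `negative_delta` flag marking a likely optimizer failure when the full
#'   model fits worse than the nested one.
#' @export
likelihood_ratio_test <- function(full_fit, nested_fit, df = NULL) {
  if (!spec_is_nested(nested_fit$spec, full_fit$spec))
    stop("models are not nested: '", nested_fit$spec$name,
         "' is not a constrained version of '", full_fit$spec$name, "'")
  if (is.null(df))
    df <- length(full_fit$spec$free) - length(nested_fit$spec$free)
  delta <- full_fit$logLik - nested_fit$logLik
  stat <- 2 * delta
  list(statistic = stat, df = df,
       p_value = pchisq(max(stat, 0), df, lower.tail = FALSE),
       negative_delta = delta < 0)
}

#' Per-choice predictive probability and test against chance
#'
#' Summarizes a model's predictive adequacy as the geometric mean probability
#' assigned to each realized choice, `exp(logL / n)`, and tests it against
#' the 0.5 chance level of a two-option choice with a one-sided binomial
#' tail at the implied success count.
#'
#' @param total_logL summed log-likelihood over all choices.
#' @param n_choices number of choices (>= 1).
#' @return list with `prob` (geometric-mean per-choice probability) and
#'   `p_value`.
#' @export
predictive_probability <- function(total_logL, n_choices) {
  if (n_choices < 1) stop("n_choices must be >= 1")
  gm <- exp(total_logL / n_choices)
  k <- round(gm * n_choices)
  p <- pbinom(k - 1, n_choices, 0.5, lower.tail = FALSE)
  list(prob = gm, p_value = p)
}
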
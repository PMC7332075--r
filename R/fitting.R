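TRANSFORM_KIND <- c(alpha1 = "logistic", alpha2 = "logistic",
                    beta1 = "log", beta2 = "log",
                    kappa1 = "identity", kappa2 = "identity",
                    lambda = "logistic", omega = "logistic",
                    zeta = "logistic",
                    L1 = "identity", L2 = "identity", L3 = "identity")

#' Parameter transforms between natural and unconstrained space
#'
#' Bounded parameters are fitted in an unconstrained space: a logistic
#' transform for (0,1)-bounded parameters (learning rates, eligibility trace,
#' the model-sensitive weight, the Forward3 weight), a log transform for the
#' positive inverse temperatures, and identity for the unbounded
#' perseveration and boost parameters.
#'
#' @param spec a [model_spec()].
#' @return list with `to_unconstrained(x)` and `to_natural(y)`, both acting
#'   on named vectors over the spec's free parameters, and the `kind` per
#'   parameter.
#' @export
param_transforms <- function(spec) {
  kind <- TRANSFORM_KIND[spec$free]
  to_u <- function(x) {
    x <- x[spec$free]
    y <- x
    lg <- kind == "logistic"
    y[lg] <- qlogis(clamp(x[lg], 1e-10, 1 - 1e-10))
    y[kind == "log"] <- log(pmax(x[kind == "log"], 1e-12))
    y
  }
  to_n <- function(y) {
    y <- y[spec$free]
    x <- y
    x[kind == "logistic"] <- plogis(y[kind == "logistic"])
    x[kind == "log"] <- exp(y[kind == "log"])
    x
  }
  list(to_unconstrained = to_u, to_natural = to_n, kind = kind)
}

# align prior vectors with the spec's free parameters (accepts unnamed
# vectors already in spec order)
align_prior <- function(prior, spec) {
  pick <- function(v) {
    if (is.null(names(v))) {
      if (length(v) != length(spec$free))
        stop("prior length does not match the spec's free parameters")
      return(setNames(v, spec$free))
    }
    if (!all(spec$free %in% names(v)))
      stop("prior missing parameter(s): ",
           paste(setdiff(spec$free, names(v)), collapse = ", "))
    v[spec$free]
  }
  list(mu = pick(prior$mu), sigma = pick(prior$sigma))
}

# fast path: negative log-likelihood from an encoded trial matrix and a
# transformed free-parameter vector
nll_encoded <- function(theta_t, enc, spec, codes, tr) {
  if (any(!is.finite(theta_t))) return(1e10)
  # generous box in transformed space: the objective is exact inside
  # |theta| <= 8 (e.g. beta <= e^8); a quadratic barrier outside keeps the
  # search away from the flat likelihood plateaus at extreme parameters
  excess <- pmax(abs(theta_t) - 8, 0)
  barrier <- 100 * sum(excess^2)
  theta_t <- pmin(pmax(theta_t, -8), 8)
  free <- tr$to_natural(setNames(theta_t, spec$free))
  full <- setNames(numeric(12), PARAM_NAMES)
  full[names(spec$fixed)] <- spec$fixed
  full[spec$free] <- free
  for (sl in names(spec$tied)) full[sl] <- full[spec$tied[[sl]]]
  lp <- cpp_session_logp(enc, full, codes$mf, codes$ms, codes$hplus)
  v <- -sum(lp, na.rm = TRUE) + barrier
  if (!is.finite(v)) 1e10 else v
}

#' Session negative log-likelihood
#'
#' Minus the summed log-probabilities of all realized first- and second-stage
#' choices in the session under the model. Forced stages contribute 0 and
#' error trials are skipped entirely, without resetting the learner's state.
#'
#' @param params named numeric vector covering the spec's free parameters
#'   (natural space).
#' @param session a `session_data` data frame.
#' @param spec a [model_spec()].
#' @return scalar negative log-likelihood.
#' @export
session_negloglik <- function(params, session, spec) {
  full <- spec_full_params(spec, params)
  codes <- spec_codes(spec)
  lp <- cpp_session_logp(encode_session(session), full,
                         codes$mf, codes$ms, codes$hplus)
  -sum(lp, na.rm = TRUE)
}

# number of likelihood-contributing choices in a session
n_free_choices <- function(session) {
  ok <- session$error_code == "none"
  sum(ok & session$forced_stage != 1) + sum(ok & session$forced_stage != 2)
}

default_start <- function(spec) setNames(numeric(length(spec$free)), spec$free)

optimize_objective <- function(fn, starts, hessian_at_best = FALSE) {
  best <- NULL
  best_idx <- NA_integer_
  for (i in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[i]], fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) { best <- res; best_idx <- i }
  }
  if (is.null(best)) stop("all optimization restarts failed")
  if (hessian_at_best) {
    H <- tryCatch(optim(best$par, fn, method = "BFGS",
                        control = list(maxit = 1), hessian = TRUE)$hessian,
                  error = function(e) NULL)
    best$hessian <- H
  }
  best$restart <- best_idx
  best
}

#' Fixed-effects maximum-likelihood fit of one session
#'
#' Minimizes the session negative log-likelihood by quasi-Newton search in
#' the unconstrained parameter space, taking the best of `n_restarts` local
#' optimizations (the first from a neutral default start, the rest from
#' standard-normal draws in transformed space). Deterministic given `seed`.
#'
#' @param session a `session_data` data frame.
#' @param spec a [model_spec()].
#' @param n_restarts number of optimizer starts (>= 1).
#' @param seed optional integer seed.
#' @return list with `params` (natural space), `params_t` (transformed),
#'   `nll`, `logLik`, `n_obs` (free choices), `spec`, and `diagnostics`.
#' @export
fit_ml_session <- function(session, spec, n_restarts = 20, seed = NULL) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_session(session)
  codes <- spec_codes(spec)
  tr <- param_transforms(spec)
  k <- length(spec$free)
  fn <- function(h) nll_encoded(h, enc, spec, codes, tr)
  starts <- c(list(default_start(spec)),
              lapply(seq_len(n_restarts - 1),
                     function(i) setNames(rnorm(k, 0, 1.5), spec$free)))
  best <- optimize_objective(fn, starts)
  params_t <- setNames(best$par, spec$free)
  list(params = tr$to_natural(params_t), params_t = params_t,
       nll = best$value, logLik = -best$value,
       n_obs = n_free_choices(session), spec = spec,
       diagnostics = list(restart = best$restart,
                          convergence = best$convergence))
}

#' E-step: per-session MAP estimates under the empirical prior
#'
#' For each session, maximizes the log posterior (session log-likelihood plus
#' the Gaussian prior in transformed space), taking the best of `n_restarts`
#' optimizations: one warm-started from `warm_start` (the previous EM
#' iteration's estimate, or the fixed-effects fit), the rest from draws from
#' the prior. Posterior variances come from the diagonal of the inverse
#' Hessian at the maximum (Laplace approximation); a non-positive-definite
#' Hessian falls back to the reciprocal diagonal and is flagged.
#'
#' @param sessions list of `session_data` frames.
#' @param prior list with numeric `mu` and `sigma` named by free parameter
#'   (transformed space).
#' @param spec a [model_spec()].
#' @param n_restarts optimizer starts per session (default 101: one warm
#'   start plus 100 prior draws).
#' @param warm_start optional matrix (parameters x sessions) of transformed
#'   warm starts.
#' @param seed optional integer seed.
#' @return list of per-session fits: `m` (MAP, transformed), `S` (posterior
#'   variances), `map_params` (natural), `nll` (data term at MAP),
#'   `logpost`, `hessian_ok`, `restart`.
#' @export
em_estep <- function(sessions, prior, spec, n_restarts = 101,
                     warm_start = NULL, seed = NULL) {
  prior <- align_prior(prior, spec)
  if (any(prior$sigma <= 0)) stop("prior standard deviations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  codes <- spec_codes(spec)
  tr <- param_transforms(spec)
  k <- length(spec$free)
  mu <- prior$mu; sg <- prior$sigma
  lapply(seq_along(sessions), function(i) {
    enc <- encode_session(sessions[[i]])
    fn <- function(h) {
      nll_encoded(h, enc, spec, codes, tr) + 0.5 * sum(((h - mu) / sg)^2)
    }
    w <- if (!is.null(warm_start)) warm_start[, i] else mu
    starts <- c(list(setNames(w, spec$free)),
                lapply(seq_len(n_restarts - 1),
                       function(j) setNames(rnorm(k, mu, sg), spec$free)))
    best <- optimize_objective(fn, starts, hessian_at_best = TRUE)
    m <- setNames(best$par, spec$free)
    S <- rep(NA_real_, k)
    hessian_ok <- FALSE
    if (!is.null(best$hessian)) {
      Sinv <- tryCatch(solve(best$hessian), error = function(e) NULL)
      if (!is.null(Sinv) && all(diag(Sinv) > 0)) {
        S <- diag(Sinv)
        hessian_ok <- TRUE
      } else {
        d <- diag(best$hessian)
        S <- ifelse(d > 0, 1 / d, 1e-6)
      }
    } else S <- rep(1e-6, k)
    names(S) <- spec$free
    nll_data <- nll_encoded(m, enc, spec, codes, tr)
    list(m = m, S = S, map_params = tr$to_natural(m), nll = nll_data,
         logpost = -best$value, hessian_ok = hessian_ok,
         restart = best$restart, n_obs = n_free_choices(sessions[[i]]))
  })
}

#' M-step: update the empirical-prior hyperparameters
#'
#' Sets the prior mean to the average MAP estimate and the prior variance to
#' the average second moment (MAP squared plus Laplace posterior variance)
#' minus the squared mean. Numerically non-positive variances are floored at
#' a small positive value with a warning.
#'
#' @param fits output of [em_estep()].
#' @return list with `mu`, `sigma` (transformed space) and `floored`.
#' @export
em_mstep <- function(fits) {
  m <- sapply(fits, `[[`, "m")
  S <- sapply(fits, `[[`, "S")
  if (is.null(dim(m))) { m <- matrix(m, nrow = 1); S <- matrix(S, nrow = 1) }
  mu <- rowMeans(m)
  sigma2 <- rowMeans(m^2 + S) - mu^2
  floored <- sigma2 <= 1e-8
  if (any(floored)) {
    warning("prior variance floored for: ",
            paste(names(mu)[floored], collapse = ", "))
    sigma2[floored] <- 1e-8
  }
  list(mu = mu, sigma = sqrt(sigma2), floored = floored)
}

#' Mixed-effects empirical-Bayes fit across sessions
#'
#' Expectation-maximization over the session-level Gaussian empirical prior:
#' the E-step computes per-session MAP estimates and Laplace posterior
#' variances under the current prior ([em_estep()]); the M-step re-estimates
#' the prior mean and SD ([em_mstep()]). The prior is initialised from the
#' trimmed mean and variance of the per-session maximum-likelihood fits
#' (default 25% total trimming, i.e. 12.5% per tail). Iterations stop when
#' the largest absolute change in any session's MAP estimate falls below
#' `tol`, after which a final E-step is run.
#'
#' @param sessions list of `session_data` frames.
#' @param spec a [model_spec()].
#' @param n_restarts_ml restarts for the initializing fixed-effects fits.
#' @param n_restarts_e restarts per session and EM iteration.
#' @param max_iter iteration cap; hitting it returns the best fit with
#'   `converged = FALSE`.
#' @param tol convergence threshold on MAP changes (transformed space).
#' @param trim_total total trimmed fraction for the initial moments; set
#'   `trim_per_tail = TRUE` to read it as a per-tail fraction instead.
#' @param trim_per_tail see `trim_total`.
#' @param seed optional integer seed.
#' @return object of class `eb_fit`: `prior` (converged hyperparameters, both
#'   transformed and natural-space prior means), `fits` (final E-step),
#'   `spec`, `n_iter`, `converged`, `history` of prior means.
#' @export
fit_empirical_bayes <- function(sessions, spec, n_restarts_ml = 20,
                                n_restarts_e = 101, max_iter = 50,
                                tol = 0.005, trim_total = 0.25,
                                trim_per_tail = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ml <- lapply(sessions, fit_ml_session, spec = spec,
               n_restarts = n_restarts_ml)
  m0 <- sapply(ml, `[[`, "params_t")
  if (is.null(dim(m0))) m0 <- matrix(m0, nrow = 1,
                                     dimnames = list(spec$free, NULL))
  trim <- if (trim_per_tail) trim_total else trim_total / 2
  mom <- apply(m0, 1, function(x) unlist(trimmed_moments(x, trim)))
  # initialization only: keep the starting prior proper and moderately wide
  prior <- list(mu = setNames(clamp(mom["mean", ], -8, 8), spec$free),
                sigma = setNames(clamp(sqrt(pmax(mom["var", ], 1e-4)),
                                       1e-2, 2.5), spec$free))
  warm <- m0
  history <- list()
  converged <- FALSE
  iter <- 0
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1
    fits <- em_estep(sessions, prior, spec, n_restarts = n_restarts_e,
                     warm_start = warm)
    m <- sapply(fits, `[[`, "m")
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    delta <- max(abs(m - warm))
    warm <- m
    prior <- em_mstep(fits)
    history[[iter]] <- prior$mu
    if (delta < tol) { converged <- TRUE; break }
  }
  fits <- em_estep(sessions, prior, spec, n_restarts = n_restarts_e,
                   warm_start = warm)
  tr <- param_transforms(spec)
  structure(list(
    prior = c(prior, list(mu_natural = tr$to_natural(prior$mu))),
    fits = fits, spec = spec, n_iter = iter, converged = converged,
    delta = delta, ml_fits = ml,
    history = do.call(rbind, history)), class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat("Empirical-Bayes fit:", x$spec$name, "|", length(x$fits), "sessions |",
      x$n_iter, "EM iterations",
      if (x$converged) "(converged)" else "(iteration cap hit)", "\n")
  cat("Prior means (natural space):\n")
  print(round(x$prior$mu_natural, 4))
  invisible(x)
}
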
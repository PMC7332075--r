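#' Stay probability by previous outcome level and transition
#'
#' Probability of repeating the previous first-stage choice, tabulated by the
#' previous trial's outcome level and transition type. Consecutive pairs are
#' formed over the analyzed-trial sequence (error and forced trials excluded
#' first). Cells with no observations are `NA`, never 0.
#'
#' @param sessions list of `session_data` frames (or a single one).
#' @param drop_forced,drop_errors exclusion toggles, see [analyzed_trials()].
#' @return list with `mean` and `sem` (3 x 2 matrices, outcome level x
#'   transition, averaged across sessions) and `per_session` (long data
#'   frame: session, level, transition, n, p_repeat).
#' @export
stay_table <- function(sessions, drop_forced = TRUE, drop_errors = TRUE) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  rows <- list()
  for (s in sessions) {
    d <- analyzed_trials(s, drop_forced, drop_errors)
    if (nrow(d) < 2) next
    n <- nrow(d)
    stay <- d$a1[-1] == d$a1[-n]
    lev <- d$outcome_level[-n]
    trans <- d$transition[-n]
    for (L in 1:3) for (tt in c("common", "rare")) {
      idx <- lev == L & trans == tt
      rows[[length(rows) + 1]] <- data.frame(
        session = d$session_id[1], level = L, transition = tt,
        n = sum(idx), p_repeat = if (any(idx)) mean(stay[idx]) else NA_real_)
    }
  }
  per <- do.call(rbind, rows)
  agg <- function(f) {
    m <- matrix(NA_real_, 3, 2,
                dimnames = list(c("low", "medium", "high"),
                                c("common", "rare")))
    for (L in 1:3) for (j in 1:2) {
      tt <- c("common", "rare")[j]
      v <- per$p_repeat[per$level == L & per$transition == tt]
      v <- v[!is.na(v)]
      if (length(v)) m[L, j] <- f(v)
    }
    m
  }
  list(mean = agg(mean),
       sem = agg(function(v) sd(v) / sqrt(length(v))),
       per_session = per)
}

centre_scale <- function(x, continuous) {
  x <- x - mean(x)
  if (continuous) {
    s <- sd(x)
    if (s > 0) x <- x / (2 * s)
  }
  x
}

#' Lagged design matrix for the first-stage choice regression
#'
#' Builds, per session, the logistic-regression design predicting the current
#' first-stage choice (`C = 1` for action x, the "car" picture role) from the
#' previous `n_lags` analyzed trials. Base variables are C (choice, binary),
#' R (outcome level 1/2/3, treated as continuous) and T (transition, rare = 1,
#' common = 0). All are mean-centred within session and continuous variables
#' are additionally scaled by twice their SD, before interaction terms are
#' formed. Per lag the predictors are C, R, T, RxT, RxC, TxC and RxTxC; with
#' the constant the model has `1 + 7 * n_lags` coefficients.
#'
#' Lags index the analyzed-trial sequence: excluded (error/forced) trials are
#' removed before lagging by default; `calendar_lags = TRUE` instead lags
#' over the raw trial sequence and drops responses whose history contains
#' excluded trials.
#'
#' @param sessions list of `session_data` frames (or one).
#' @param n_lags number of lags (default 5).
#' @param calendar_lags lag over the raw trial sequence instead.
#' @return data frame with `session_id`, response `y`, and the predictor
#'   columns; degenerate (constant) columns are listed in attribute
#'   `"degenerate"`.
#' @export
build_choice_design <- function(sessions, n_lags = 5, calendar_lags = FALSE) {
  base_terms <- c("C", "R", "T", "RxT", "RxC", "TxC", "RxTxC")
  out <- lapply(session_list(sessions), function(s) {
    d <- design_base(s, calendar_lags)
    if (nrow(d) < n_lags + 1) return(NULL)
    C <- centre_scale(d$C, FALSE)
    R <- centre_scale(d$R, TRUE)
    T_ <- centre_scale(d$T, FALSE)
    terms <- list(C = C, R = R, T = T_, RxT = R * T_, RxC = R * C,
                  TxC = T_ * C, RxTxC = R * T_ * C)
    rows <- (n_lags + 1):nrow(d)
    keep <- if (calendar_lags) d$usable[rows] &
      vapply(rows, function(t) all(d$usable[(t - n_lags):(t - 1)]),
             logical(1)) else rep(TRUE, length(rows))
    X <- do.call(cbind, lapply(seq_len(n_lags), function(i) {
      m <- sapply(terms, function(v) v[rows - i])
      colnames(m) <- paste0(base_terms, "_lag", i)
      m
    }))
    data.frame(session_id = d$session_id[rows][keep],
               y = d$C[rows][keep],
               X[keep, , drop = FALSE], check.names = FALSE)
  })
  assemble_design(out, n_lags)
}

#' Lagged design matrix for the reaction-time regressions
#'
#' Linear-regression design for a preprocessed response (see
#' [preprocess_rt()]): a fatigue term (the centred, 2-SD-scaled trial index)
#' plus, per lag, R, T and RxT — the choice interactions are deliberately
#' absent. With the constant the model has `2 + 3 * n_lags` coefficients.
#'
#' @inheritParams build_choice_design
#' @param response name of the preprocessed response column (e.g. `"rt1_z"`
#'   or `"fixrt_z"`).
#' @return data frame as in [build_choice_design()].
#' @export
build_rt_design <- function(sessions, n_lags = 5, response = "rt1_z",
                            calendar_lags = FALSE) {
  out <- lapply(session_list(sessions), function(s) {
    if (!response %in% names(s))
      stop("response column '", response, "' not found; run preprocess_rt()")
    d <- design_base(s, calendar_lags, extra = response)
    if (nrow(d) < n_lags + 1) return(NULL)
    R <- centre_scale(d$R, TRUE)
    T_ <- centre_scale(d$T, FALSE)
    fatigue <- centre_scale(seq_len(nrow(d)), TRUE)
    terms <- list(R = R, T = T_, RxT = R * T_)
    rows <- (n_lags + 1):nrow(d)
    keep <- !is.na(d[[response]][rows])
    if (calendar_lags)
      keep <- keep & d$usable[rows] &
        vapply(rows, function(t) all(d$usable[(t - n_lags):(t - 1)]),
               logical(1))
    X <- do.call(cbind, lapply(seq_len(n_lags), function(i) {
      m <- sapply(terms, function(v) v[rows - i])
      colnames(m) <- paste0(c("R", "T", "RxT"), "_lag", i)
      m
    }))
    data.frame(session_id = d$session_id[rows][keep],
               y = d[[response]][rows][keep],
               fatigue = fatigue[rows][keep],
               X[keep, , drop = FALSE], check.names = FALSE)
  })
  assemble_design(out, n_lags)
}

session_list <- function(sessions) {
  if (inherits(sessions, "session_data") || is.data.frame(sessions))
    list(sessions) else sessions
}

design_base <- function(s, calendar_lags, extra = NULL) {
  d <- if (calendar_lags) s else analyzed_trials(s)
  usable <- d$error_code == "none" & d$forced_stage == 0
  base <- data.frame(session_id = d$session_id,
                     C = as.numeric(d$a1 == "x"),
                     R = as.numeric(d$outcome_level),
                     T = as.numeric(d$transition == "rare"),
                     usable = usable)
  if (calendar_lags) {
    # masked history rows keep neutral values; responses there are dropped
    base$C[!usable] <- 0; base$R[!usable] <- 2; base$T[!usable] <- 0
  }
  for (e in extra) base[[e]] <- d[[e]]
  base
}

assemble_design <- function(parts, n_lags) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    stop("no session has enough trials for a ", n_lags, "-lag design")
  design <- do.call(rbind, parts)
  pred <- setdiff(names(design), c("session_id", "y"))
  degen <- pred[vapply(pred, function(cn) sd(design[[cn]]) == 0, logical(1))]
  attr(design, "degenerate") <- degen
  attr(design, "n_lags") <- n_lags
  design
}

# penalized logistic fallback for separated sessions (small ridge on slopes)
ridge_logistic <- function(X, y, lambda = 1e-2) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * lambda * sum(b[-1]^2)
  }
  fit <- optim(numeric(ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500))
  eta <- drop(X %*% fit$par)
  p <- plogis(eta)
  W <- p * (1 - p)
  H <- crossprod(X * sqrt(W)) + diag(c(0, rep(lambda, ncol(X) - 1)))
  se <- sqrt(diag(solve(H)))
  list(coef = setNames(fit$par, colnames(X)), se = se)
}

fit_fixed <- function(design, family) {
  pred <- setdiff(names(design), c("session_id", "y"))
  split_d <- split(design, design$session_id)
  terms <- c("(Intercept)", pred)
  co <- se <- pv <- matrix(NA_real_, length(split_d), length(terms),
                           dimnames = list(names(split_d), terms))
  flags <- character(0)
  for (i in seq_along(split_d)) {
    d <- split_d[[i]]
    X <- cbind(`(Intercept)` = 1, as.matrix(d[pred]))
    if (family == "binomial") {
      fit <- suppressWarnings(glm(y ~ ., data = d[c("y", pred)],
                                  family = binomial()))
      separated <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)
      if (separated) {
        flags <- c(flags, paste0(names(split_d)[i], ": penalized (separation)"))
        rf <- ridge_logistic(X, d$y)
        co[i, ] <- rf$coef; se[i, ] <- rf$se
        pv[i, ] <- 2 * stats::pnorm(-abs(rf$coef / rf$se))
        next
      }
    } else {
      fit <- lm(y ~ ., data = d[c("y", pred)])
    }
    sm <- summary(fit)$coefficients
    co[i, rownames(sm)] <- sm[, 1]
    se[i, rownames(sm)] <- sm[, 2]
    pv[i, rownames(sm)] <- sm[, 4]
  }
  est <- colMeans(co, na.rm = TRUE)
  n_s <- colSums(!is.na(co))
  sem <- apply(co, 2, function(v) sd(v, na.rm = TRUE)) / sqrt(n_s)
  tstat <- est / sem
  pt2 <- 2 * pt(-abs(tstat), df = pmax(n_s - 1, 1))
  structure(list(
    coefficients = co, se = se, p_values = pv,
    summary = data.frame(term = terms, mean = est, sem = sem, t = tstat,
                         p = pt2, n_sessions = n_s, row.names = NULL),
    family = family, flags = flags), class = "fixed_reg")
}

#' Per-session (fixed-effects) logistic regression
#'
#' Fits the logistic model independently to each session and summarizes each
#' coefficient across sessions with a two-tailed one-sample t-test against 0.
#' Sessions showing separation are refitted with a small ridge penalty and
#' flagged.
#'
#' @param design output of [build_choice_design()].
#' @return object of class `fixed_reg`: per-session `coefficients`, `se`,
#'   `p_values`, an across-session `summary` table, and `flags`.
#' @export
fit_logistic_fixed <- function(design) fit_fixed(design, "binomial")

#' Per-session (fixed-effects) linear regression
#'
#' Linear analogue of [fit_logistic_fixed()] for reaction-time designs.
#'
#' @param design output of [build_rt_design()].
#' @return a `fixed_reg` object.
#' @export
fit_linear_fixed <- function(design) fit_fixed(design, "gaussian")

#' Contrast between two coefficients across sessions
#'
#' Paired t-test across sessions of the (by default absolute) difference
#' between two per-session coefficients — e.g. whether the reward x
#' transition interaction outweighs the reward main effect.
#'
#' @param fit a `fixed_reg` object.
#' @param term_a,term_b coefficient names.
#' @param absolute compare magnitudes rather than signed values.
#' @return list with `mean_diff`, `t`, `df`, `p_value`.
#' @export
coef_contrast <- function(fit, term_a, term_b, absolute = TRUE) {
  a <- fit$coefficients[, term_a]
  b <- fit$coefficients[, term_b]
  if (absolute) { a <- abs(a); b <- abs(b) }
  d <- a - b
  d <- d[!is.na(d)]
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(mean_diff = mean(d), t = tstat, df = n - 1,
       p_value = 2 * pt(-abs(tstat), n - 1))
}

#' Preprocess reaction times for regression
#'
#' First-stage reaction times are log-transformed and z-scored within session
#' and response side (sides differ systematically in latency); fixation
#' latencies are log-transformed and z-scored within session only. Points
#' more than three SDs from the individual mean are removed (`NA`). Sides
#' with fewer than two observations are excluded with a warning.
#'
#' @param sessions list of `session_data` frames (or one).
#' @param kind `"rt1"` (side-wise) or `"fixrt"`.
#' @return the sessions with an added `rt1_z` or `fixrt_z` column.
#' @export
preprocess_rt <- function(sessions, kind = c("rt1", "fixrt")) {
  kind <- match.arg(kind)
  single <- inherits(sessions, "session_data")
  sessions <- session_list(sessions)
  out <- lapply(sessions, function(s) {
    raw <- if (kind == "rt1") s$rt1 else s$fix_rt
    if (any(raw <= 0, na.rm = TRUE)) stop("reaction times must be positive")
    lx <- log(raw)
    grp <- if (kind == "rt1") s$side1 else rep("all", nrow(s))
    z <- rep(NA_real_, nrow(s))
    for (g in unique(grp)) {
      idx <- grp == g & !is.na(lx)
      if (sum(idx) < 2) {
        if (sum(idx) > 0)
          warning("side '", g, "' has < 2 observations; excluded")
        next
      }
      z[idx] <- (lx[idx] - mean(lx[idx])) / sd(lx[idx])
    }
    z[!is.na(z) & abs(z) > 3] <- NA
    s[[paste0(sub("fix_rt", "fixrt", kind), "_z")]] <- z
    s
  })
  if (single) out[[1]] else out
}

#' Exponential decay fit over lag coefficients
#'
#' Least-squares fit of `A * exp(b * lag)` to the mean fixed-effects
#' coefficient at each lag. `b` is the decay constant (negative for
#' magnitudes that fade with lag). Fitted by a profile grid over `b` (the
#' amplitude has a closed form given `b`) polished with
#' [minpack.lm::nlsLM()]. Sign-alternating input yields a fit with low
#' adjusted R-squared, not an error.
#'
#' @param mean_coefficients numeric vector of per-lag coefficients
#'   (lags `1..length`).
#' @param lags lag values (default `seq_along`).
#' @return object of class `decay_fit`: `A`, `b`, `r2`, `adj_r2`, `fitted`.
#' @export
fit_decay <- function(mean_coefficients, lags = seq_along(mean_coefficients)) {
  y <- as.numeric(mean_coefficients)
  n <- length(y)
  if (n < 3) stop("need at least 3 lag values")
  if (sd(y) == 0)
    return(structure(list(A = y[1], b = 0, r2 = NA_real_, adj_r2 = NA_real_,
                          fitted = y), class = "decay_fit"))
  prof <- function(b) {
    e <- exp(b * lags)
    A <- sum(y * e) / sum(e * e)
    c(A = A, rss = sum((y - A * e)^2))
  }
  grid <- seq(-4, 4, by = 0.005)
  rss <- vapply(grid, function(b) prof(b)["rss"], numeric(1))
  b0 <- grid[which.min(rss)]
  A0 <- prof(b0)["A"]
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ A * exp(b * lag),
                        data = data.frame(y = y, lag = lags),
                        start = list(A = unname(A0), b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    A <- coef(fit)[["A"]]; b <- coef(fit)[["b"]]
  } else { A <- unname(A0); b <- b0 }
  fv <- A * exp(b * lags)
  rss_f <- sum((y - fv)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss_f / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(A = A, b = b, r2 = r2, adj_r2 = adj, fitted = fv),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: A = %.4f, b = %.4f, adj R^2 = %.3f\n",
              x$A, x$b, x$adj_r2))
  invisible(x)
}

#' Mixed-effects (random-coefficient) regression across sessions
#'
#' Treats each regression coefficient as a random effect across sessions,
#' using the two-stage summary approach: per-session fixed-effects fits
#' followed by a random-effects pooling of each coefficient
#' ([metafor::rma.uni()], DerSimonian-Laird). Coefficients whose
#' random-effects fit does not converge fall back to the fixed-effects
#' summary and are flagged.
#'
#' @param design a design from [build_choice_design()] or [build_rt_design()].
#' @param family `"logistic"` or `"linear"`.
#' @return object of class `mixed_reg`: pooled `summary` (estimate, se, z, p,
#'   tau2 per term), the underlying `fixed` fit, and `flags`.
#' @export
fit_mixed_regression <- function(design, family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (length(unique(design$session_id)) < 2)
    stop("mixed-effects pooling needs >= 2 sessions")
  fx <- fit_fixed(design, if (family == "logistic") "binomial" else "gaussian")
  terms <- colnames(fx$coefficients)
  flags <- character(0)
  rows <- lapply(terms, function(tm) {
    yi <- fx$coefficients[, tm]; sei <- fx$se[, tm]
    ok <- is.finite(yi) & is.finite(sei) & sei > 0
    re <- tryCatch(metafor::rma.uni(yi = yi[ok], sei = sei[ok],
                                    method = "DL"),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(re)) {
      flags <<- c(flags, tm)
      i <- match(tm, fx$summary$term)
      return(data.frame(term = tm, estimate = fx$summary$mean[i],
                        se = fx$summary$sem[i], z = fx$summary$t[i],
                        p = fx$summary$p[i], tau2 = NA_real_))
    }
    data.frame(term = tm, estimate = as.numeric(re$beta),
               se = re$se, z = re$zval, p = re$pval, tau2 = re$tau2)
  })
  structure(list(summary = do.call(rbind, rows), fixed = fx,
                 family = family, backend = "two-stage DL", flags = flags),
            class = "mixed_reg")
}

#' Wald test on a set of mixed-effects coefficients
#'
#' Chi-squared test that the named pooled coefficients are jointly zero
#' (independence working assumption across terms).
#'
#' @param fit a `mixed_reg` object.
#' @param terms coefficient names to test jointly.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, terms) {
  s <- fit$summary[fit$summary$term %in% terms, ]
  if (!nrow(s)) stop("no matching terms")
  stat <- sum((s$estimate / s$se)^2)
  list(statistic = stat, df = nrow(s),
       p_value = pchisq(stat, nrow(s), lower.tail = FALSE))
}
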
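PARAM_NAMES <- c("alpha1", "alpha2", "beta1", "beta2", "kappa1", "kappa2",
                 "lambda", "omega", "zeta", "L1", "L2", "L3")

TIE_CHOICES <- c("alpha1=alpha2", "beta1=beta2", "kappa1=kappa2",
                 "kappa1=0", "kappa2=0", "lambda=0")

#' Specify a reinforcement-learning model
#'
#' A model specification names the model-free temporal-difference variant
#' (SARSA evaluates the successor state by the action actually taken;
#' Q-learning by the best available action), the model-sensitive transition
#' learner (`Forward1` knows the true 70/30 structure; `Forward2` assigns 0.7
#' to the more frequently observed action-state mapping; `Forward3` weighs a
#' structured 70/30 account against an uninformative 50/50 one with weight
#' `zeta`), whether the Hybrid+ one-trial outcome-dependent boost is active,
#' and any parameter tying/zeroing constraints.
#'
#' Pure model-free specifications fix the model-sensitive weight `omega` at 0,
#' pure model-sensitive ones at 1; a Hybrid (both components) leaves `omega`
#' free. Hybrid+ requires both components.
#'
#' @param mf model-free variant: `"SARSA"`, `"Q"`, or `"none"`.
#' @param ms model-sensitive variant: `"Forward1"`, `"Forward2"`,
#'   `"Forward3"`, or `"none"`.
#' @param hybrid_plus logical; add the outcome-level boost parameters
#'   `L1` (high), `L2` (medium), `L3` (low).
#' @param ties character subset of `"alpha1=alpha2"`, `"beta1=beta2"`,
#'   `"kappa1=kappa2"`, `"kappa1=0"`, `"kappa2=0"`, `"lambda=0"`.
#' @param name optional label used in reports.
#' @return an object of class `model_spec` with the derived free-parameter
#'   list (`$free`), fixed values (`$fixed`), and tied pairs (`$tied`).
#' @examples
#' model_spec("SARSA", "none")$free
#' model_spec("SARSA", "Forward1", hybrid_plus = TRUE,
#'            ties = c("alpha1=alpha2", "kappa1=kappa2", "lambda=0"))$free
#' @export
model_spec <- function(mf = c("SARSA", "Q", "none"),
                       ms = c("none", "Forward1", "Forward2", "Forward3"),
                       hybrid_plus = FALSE, ties = character(),
                       name = NULL) {
  mf <- match.arg(mf)
  ms <- match.arg(ms)
  bad <- setdiff(ties, TIE_CHOICES)
  if (length(bad)) stop("unknown tie constraint(s): ", paste(bad, collapse = ", "))
  if (mf == "none" && ms == "none") stop("at least one learning system required")
  if (hybrid_plus && (mf == "none" || ms == "none"))
    stop("Hybrid+ requires both a model-free and a model-sensitive component")

  fixed <- c(zeta = 0.5, L1 = 0, L2 = 0, L3 = 0)
  free <- c("alpha2", "beta1", "beta2", "kappa1", "kappa2")
  if (mf == "none") {
    fixed <- c(fixed, omega = 1, alpha1 = 0, lambda = 0)
  } else if (ms == "none") {
    fixed <- c(fixed, omega = 0)
    free <- c(free, "alpha1", "lambda")
  } else {
    free <- c(free, "alpha1", "lambda", "omega")
  }
  if (ms == "Forward3") {
    fixed <- fixed[names(fixed) != "zeta"]
    free <- c(free, "zeta")
  }
  if (hybrid_plus) {
    fixed <- fixed[!names(fixed) %in% c("L1", "L2", "L3")]
    free <- c(free, "L1", "L2", "L3")
  }
  tied <- list()
  for (tie in ties) {
    parts <- strsplit(tie, "=", fixed = TRUE)[[1]]
    lhs <- parts[1]; rhs <- parts[2]
    if (rhs == "0") {
      if (lhs %in% free) { free <- setdiff(free, lhs); fixed[lhs] <- 0 }
    } else if (lhs %in% free && rhs %in% free) {
      # the first-listed parameter stays free; the other is tied to it
      slave <- rhs; master <- lhs
      if (master %in% names(tied)) master <- tied[[master]]
      free <- setdiff(free, slave)
      tied[[slave]] <- master
    }
  }
  free <- PARAM_NAMES[PARAM_NAMES %in% free]
  structure(list(mf = mf, ms = ms, hybrid_plus = hybrid_plus, ties = ties,
                 free = free, fixed = fixed, tied = tied,
                 name = name %||% spec_label(mf, ms, hybrid_plus)),
            class = "model_spec")
}

spec_label <- function(mf, ms, hplus) {
  if (hplus) return("Hybrid+")
  if (mf != "none" && ms != "none") return("Hybrid")
  if (mf != "none") mf else ms
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$name, "(MF =", x$mf, "| MS =", x$ms,
      if (x$hybrid_plus) "| Hybrid+ boost" else "", ")\n")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  if (length(x$tied))
    cat("  tied:", paste(names(x$tied), "=", unlist(x$tied), collapse = ", "),
        "\n")
  invisible(x)
}

spec_codes <- function(spec) {
  list(mf = switch(spec$mf, none = 0L, SARSA = 1L, Q = 2L),
       ms = switch(spec$ms, none = 0L, Forward1 = 1L, Forward2 = 2L,
                   Forward3 = 3L),
       hplus = as.integer(spec$hybrid_plus))
}

#' Expand free parameter values to the full parameter vector
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector (or list) holding at least the spec's
#'   free parameters in natural space.
#' @return named numeric vector over all twelve model parameters, with tied
#'   and fixed entries filled in.
#' @export
spec_full_params <- function(spec, params) {
  params <- unlist(params)
  missing <- setdiff(spec$free, names(params))
  if (length(missing))
    stop("missing free parameter(s): ", paste(missing, collapse = ", "))
  full <- setNames(numeric(length(PARAM_NAMES)), PARAM_NAMES)
  full[names(spec$fixed)] <- spec$fixed
  full[spec$free] <- params[spec$free]
  for (slave in names(spec$tied)) full[slave] <- full[spec$tied[[slave]]]
  validate_params(full)
  full
}

validate_params <- function(full) {
  chk01 <- c("alpha1", "alpha2", "lambda", "omega", "zeta")
  if (any(full[chk01] < 0 | full[chk01] > 1))
    stop("alpha, lambda, omega, zeta must lie in [0, 1]")
  if (any(full[c("beta1", "beta2")] < 0))
    stop("inverse temperatures must be >= 0")
  if (any(!is.finite(full))) stop("non-finite parameter value")
  invisible(full)
}

#' Bundle a model specification with parameter values
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector of the spec's free parameters.
#' @return an object of class `rl_agent`, accepted by [run_session()].
#' @export
agent <- function(spec, params) {
  spec_full_params(spec, params)  # validates
  structure(list(spec = spec, params = unlist(params)[spec$free]),
            class = "rl_agent")
}

#' Registry of the bundled model presets
#'
#' Maps the canonical model names to their specifications: the two pure
#' model-free learners (7 free parameters each), the three pure
#' model-sensitive learners, the Hybrid mixture (SARSA + Forward1 with tied
#' learning rates and perseveration and no eligibility trace; 5 free
#' parameters) and Hybrid+ (Hybrid plus the three outcome-level boosts;
#' 8 free parameters).
#'
#' @return named list of [model_spec()] objects.
#' @export
model_registry <- function() {
  ms_ties <- c("kappa1=kappa2")
  hyb_ties <- c("alpha1=alpha2", "kappa1=kappa2", "lambda=0")
  list(
    SARSA = model_spec("SARSA", "none", name = "SARSA"),
    Q = model_spec("Q", "none", name = "Q"),
    Forward1 = model_spec("none", "Forward1", ties = ms_ties,
                          name = "Forward1"),
    Forward2 = model_spec("none", "Forward2", ties = ms_ties,
                          name = "Forward2"),
    Forward3 = model_spec("none", "Forward3", ties = ms_ties,
                          name = "Forward3"),
    Hybrid = model_spec("SARSA", "Forward1", ties = hyb_ties,
                        name = "Hybrid"),
    HybridPlus = model_spec("SARSA", "Forward1", hybrid_plus = TRUE,
                            ties = hyb_ties, name = "Hybrid+"))
}

#' Canonical generating parameter values for the model presets
#'
#' Best-fitting mixed-effects parameter means for two macaque subjects
#' performing this task, used as the package's default study conditions for
#' surrogate-data generation.
#'
#' @param model one of `"SARSA"`, `"Forward1"`, `"Hybrid"`, `"HybridPlus"`.
#' @param subject `"C"` or `"J"`.
#' @return named numeric vector over the preset's free parameters.
#' @export
preset_params <- function(model = c("HybridPlus", "Hybrid", "SARSA",
                                    "Forward1"),
                          subject = c("C", "J")) {
  model <- match.arg(model)
  subject <- match.arg(subject)
  p <- switch(model,
    SARSA = list(
      C = c(alpha1 = 0.48, alpha2 = 0.84, beta1 = 2.62, beta2 = 2.45,
            kappa1 = 0.19, kappa2 = 0.07, lambda = 0.52),
      J = c(alpha1 = 0.62, alpha2 = 0.62, beta1 = 1.93, beta2 = 0.28,
            kappa1 = 0.58, kappa2 = 0.58, lambda = 0)),
    Forward1 = list(
      C = c(alpha2 = 0.80, beta1 = 6.06, beta2 = 2.52, kappa1 = 0.06),
      J = c(alpha2 = 0.71, beta1 = 6.04, beta2 = 2.01, kappa1 = 0.08)),
    Hybrid = list(
      C = c(alpha1 = 0.82, beta1 = 6.39, beta2 = 2.50, kappa1 = 0.05,
            omega = 0.86),
      J = c(alpha1 = 0.77, beta1 = 6.97, beta2 = 1.68, kappa1 = 0.05,
            omega = 0.88)),
    HybridPlus = list(
      C = c(alpha1 = 0.78, beta1 = 4.57, beta2 = 2.54, kappa1 = 0.06,
            omega = 0.86, L1 = 0.25, L2 = -0.06, L3 = -0.08),
      J = c(alpha1 = 0.59, beta1 = 4.92, beta2 = 1.85, kappa1 = 0.04,
            omega = 0.88, L1 = 0.51, L2 = -0.10, L3 = -0.16)))
  p[[subject]]
}
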
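#' @useDynLib twostepRL, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef glm lm optim pchisq pbinom plogis qlogis rnorm runif
#'   sd var binomial setNames dnorm pt rbinom quantile na.omit vcov
#'   rgamma cor
#' @importFrom utils head read.csv write.csv
NULL

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean/var after symmetric trimming; `trim` is the per-tail fraction
trimmed_moments <- function(x, trim) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- floor(n * trim)
  if (n - 2 * k < 2) return(list(mean = mean(x), var = var(x)))
  xt <- x[(k + 1):(n - k)]
  list(mean = mean(xt), var = var(xt))
}
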
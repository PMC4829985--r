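#' Draw from a normal distribution truncated above
#'
#' Inverse-CDF sampler for \eqn{N(\mu, \sigma^2)} restricted to
#' \eqn{(-\infty, b]}, used to impute natural-log concentrations of
#' below-LOD biomarker measurements (upper bound \eqn{b = \ln} LOD).
#' Computed on the log-probability scale so draws stay accurate even when
#' the truncation point sits far into the lower tail.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal.
#' @param upper Upper truncation bound (vectorized over draws).
#' @return Numeric vector of draws, all \code{<= upper}.
#' @export
rtnorm_upper <- function(n, mean = 0, sd = 1, upper = Inf) {
  if (any(sd <= 0)) stop("rtnorm_upper: sd must be > 0")
  u <- stats::runif(n)
  z <- (upper - mean) / sd
  # log(u * Phi(z)) = log(u) + log(Phi(z)), inverted on the log scale
  lp <- log(u) + stats::pnorm(z, log.p = TRUE)
  mean + sd * stats::qnorm(lp, log.p = TRUE)
}

# log-density of the same distribution (normalized), used by log_joint
dtnorm_upper_log <- function(x, mean = 0, sd = 1, upper = Inf) {
  ifelse(x > upper, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm((upper - mean) / sd, log.p = TRUE))
}
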
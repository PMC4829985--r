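# Chain running, convergence diagnostics and posterior summarization.

# Run one chain; supports checkpoint/resume through `init` (a sampler state)
# and `rng` (a saved .Random.seed), in which case `seed` is ignored.
run_mcmc <- function(ctx, burn_in, iterations, thin = 1L, seed = 1L,
                     init = NULL, rng = NULL) {
  if (iterations <= 0) stop("run_mcmc: iterations must be > 0")
  if (is.null(init)) {
    set.seed(seed)
    st <- init_state(ctx)
  } else {
    st <- init
    if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
  }
  track <- c(colnames(ctx$X), "sigma_e", "sigma_b")
  mnar <- ctx$spec$missingness == "MNAR"
  if (mnar) track <- c(track, paste0("gamma_", names(st$gamma)))
  kept <- floor(iterations / thin)
  draws <- matrix(NA_real_, kept, length(track),
                  dimnames = list(NULL, track))
  k <- 0L
  for (it in seq_len(burn_in + iterations)) {
    gibbs_sweep(st, ctx)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      k <- k + 1L
      row <- c(st$beta, sqrt(st$sig2_e), sqrt(st$sig2_b))
      if (mnar) row <- c(row, st$gamma)
      draws[k, ] <- row
    }
  }
  list(draws = draws, state = st,
       rng = get(".Random.seed", globalenv()),
       accept = st$acc / max(st$n_sweeps, 1))
}

#' Run multiple MCMC chains
#'
#' Chains are independent: chain \code{c} uses seed \code{seeds[c]} for its
#' initialization and sampling stream.  Burn-in is discarded inside each
#' chain.
#'
#' @param ctx Model context from \code{\link{prepare_model_data}}.
#' @param burn_in,iterations,thin MCMC settings (iterations counts
#'   post-burn-in sweeps).
#' @param seeds Integer vector, one seed per chain.
#' @return List of class \code{"chain_set"}: \code{draws} (list of
#'   iteration x parameter matrices), \code{accept}, \code{states}.
#' @export
run_chains <- function(ctx, burn_in, iterations, thin = 1L, seeds = 1L) {
  if (burn_in >= burn_in + iterations && iterations <= 0)
    stop("run_chains: iterations must exceed 0")
  res <- lapply(seeds, function(s)
    run_mcmc(ctx, burn_in, iterations, thin, seed = s))
  structure(list(draws = lapply(res, `[[`, "draws"),
                 accept = lapply(res, `[[`, "accept"),
                 states = lapply(res, `[[`, "state"),
                 rng = lapply(res, `[[`, "rng"),
                 burn_in = burn_in, iterations = iterations,
                 seeds = seeds),
            class = "chain_set")
}

# --- diagnostics ------------------------------------------------------------

split_chains <- function(draws_list) {
  out <- list()
  for (d in draws_list) {
    n <- nrow(d)
    h <- floor(n / 2)
    out <- c(out, list(d[seq_len(h), , drop = FALSE],
                       d[(n - h + 1):n, , drop = FALSE]))
  }
  out
}

rhat_basic <- function(mat) {
  # mat: iterations x chains for one parameter
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2 || m < 2) return(NA_real_)
  means <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(1)  # constant draws
  sqrt(((n - 1) / n * W + B / n) / W)
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split R-hat (the modern standard); the classic
#' Gelman-Rubin statistic on the raw draws is available via
#' \code{rank_normalized = FALSE}.  Constant draws report 1.
#'
#' @param draws_list List of iteration x parameter draw matrices (one per
#'   chain), or a single matrix.
#' @param rank_normalized Use rank-normalized draws (default TRUE).
#' @return Named vector of R-hat values, one per parameter.
#' @export
rhat <- function(draws_list, rank_normalized = TRUE) {
  if (is.matrix(draws_list)) draws_list <- list(draws_list)
  halves <- split_chains(draws_list)
  pn <- colnames(halves[[1]])
  vapply(seq_along(pn), function(j) {
    mat <- vapply(halves, function(h) h[, j], numeric(nrow(halves[[1]])))
    if (!all(is.finite(mat))) return(NA_real_)
    if (diff(range(mat)) == 0) return(1)
    if (rank_normalized) {
      z <- rank_normalize(as.numeric(mat))
      mat <- matrix(z, nrow(mat), ncol(mat))
    }
    rhat_basic(mat)
  }, numeric(1), USE.NAMES = FALSE) -> out
  stats::setNames(out, pn)
}

# effective sample size by autocorrelation truncation (Geyer initial
# positive sequence), summed over chains
ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (n < 4 || !is.finite(v) || v == 0) return(n)
  lag_max <- min(n - 2, 1000)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    g <- ac[k] + ac[k + 1]
    if (g < 0) break
    s <- s + g
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Effective sample size
#'
#' @param draws_list List of draw matrices (one per chain) or one matrix.
#' @return Named vector of ESS values (summed over chains).
#' @export
ess <- function(draws_list) {
  if (is.matrix(draws_list)) draws_list <- list(draws_list)
  pn <- colnames(draws_list[[1]])
  out <- vapply(seq_along(pn), function(j)
    sum(vapply(draws_list, function(d) ess_one(d[, j]), numeric(1))),
    numeric(1))
  stats::setNames(out, pn)
}

#' Summarize posterior draws
#'
#' Equal-tailed percentile intervals; split R-hat (rank-normalized, with
#' the classic Gelman-Rubin value alongside); ESS by autocorrelation
#' truncation.  Sex x exposure product terms are flagged as showing
#' meaningful effect-measure modification when their 80% credible interval
#' excludes zero.
#'
#' @param chains A \code{chain_set}, a list of draw matrices, or a single
#'   matrix.
#' @param heterogeneity_params Parameter names to which the 80%-CI
#'   heterogeneity rule applies (default: names starting \code{"sex:"}).
#' @return \code{data.frame}: parameter, mean, sd, ci95/ci80 bounds, rhat,
#'   rhat_classic, ess, flag_heterogeneity.
#' @export
summarize_draws <- function(chains, heterogeneity_params = NULL) {
  draws_list <- if (inherits(chains, "chain_set")) chains$draws
  else if (is.matrix(chains)) list(chains) else chains
  all_draws <- do.call(rbind, draws_list)
  if (nrow(all_draws) < 100)
    stop("summarize_draws: need at least 100 retained draws")
  pn <- colnames(all_draws)
  if (is.null(heterogeneity_params))
    heterogeneity_params <- grep("^sex:", pn, value = TRUE)
  q <- t(apply(all_draws, 2, stats::quantile,
               probs = c(0.025, 0.1, 0.9, 0.975), type = 7, names = FALSE))
  rh <- rhat(draws_list)
  rhc <- rhat(draws_list, rank_normalized = FALSE)
  rhc[!is.finite(rhc)] <- 1
  out <- data.frame(parameter = pn, mean = colMeans(all_draws),
                    sd = apply(all_draws, 2, stats::sd),
                    ci95_lower = q[, 1], ci95_upper = q[, 4],
                    ci80_lower = q[, 2], ci80_upper = q[, 3],
                    rhat = as.numeric(rh), rhat_classic = as.numeric(rhc),
                    ess = as.numeric(ess(draws_list)),
                    stringsAsFactors = FALSE)
  out$flag_heterogeneity <- out$parameter %in% heterogeneity_params &
    (out$ci80_lower > 0 | out$ci80_upper < 0)
  rownames(out) <- NULL
  out
}

#' 95% prior interval implied by a precision
#'
#' A null-centred normal prior with precision \code{tau} (variance
#' \code{1/tau}) puts 95% of its mass within \code{1.96 sqrt(1/tau)} of
#' zero; on the odds-ratio scale the bounds are exponentiated.
#'
#' @param tau Prior precision (> 0).
#' @param scale \code{"linear"} or \code{"odds_ratio"}.
#' @return Numeric \code{c(lower, upper)}.
#' @export
prior_interval <- function(tau, scale = c("linear", "odds_ratio")) {
  scale <- match.arg(scale)
  if (tau <= 0) stop("prior_interval: tau must be > 0")
  hw <- 1.96 * sqrt(1 / tau)
  out <- c(lower = -hw, upper = hw)
  if (scale == "odds_ratio") out <- exp(out)
  out
}
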
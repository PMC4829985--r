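# User-facing model fitting and S3 methods.

#' Fit the Bayesian phthalate-mixture fat-mass model
#'
#' The central fitting function.  Relates prenatal urinary phthalate
#' metabolite concentrations (standardized natural logs or creatinine-
#' corrected tertiles; the four DEHP metabolites as a molar sum) to
#' repeated childhood percent fat mass via a random-intercept linear
#' mixed-effects model with null-centred shrinkage priors, handling
#' below-LOD concentrations by truncated-normal imputation inside the
#' MCMC, imputing missing covariates through dedicated submodels, and --
#' when \code{spec$missingness = "MNAR"} -- jointly fitting a logistic
#' selection model in which the probability that an outcome is missing may
#' depend on its own (unobserved) value.
#'
#' @param mothers Mother records (\code{\link{read_mothers}} or
#'   \code{\link{simulate_mothers}}).
#' @param visits Visit records (\code{\link{read_visits}} or
#'   \code{\link{simulate_visits}}).
#' @param spec A \code{\link{model_spec}}.
#' @param registry Metabolite registry.
#' @param selection A \code{\link{selection_spec}} (MNAR fits only; a
#'   default one is used if omitted).
#' @param prior_only Draw from the priors instead of the posterior (used
#'   for prior-calibration checks).
#' @param verbose Print progress.
#' @return Object of class \code{"phthalmix_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{simulate} and \code{plot}.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(truth_config(n_children = 60), seed = 1)
#' spec <- model_spec(mcmc = list(burn_in = 200, iterations = 500,
#'                                chains = 2, seed = 1))
#' fit <- phthalmix_fit(cohort$mothers, cohort$visits, spec)
#' summary(fit)
#' }
#' @export
phthalmix_fit <- function(mothers, visits, spec = model_spec(),
                          registry = default_registry(), selection = NULL,
                          prior_only = FALSE, verbose = FALSE) {
  cl <- match.call()
  if (spec$missingness == "MNAR" && is.null(selection))
    selection <- selection_spec()
  ctx <- prepare_model_data(mothers, visits, spec, registry, selection)
  if (prior_only) {
    chains <- prior_chain_set(ctx, spec)
  } else {
    n_chains <- if (spec$missingness == "MNAR")
      selection$chains else spec$mcmc$chains
    seeds <- spec$mcmc$seed + seq_len(n_chains) - 1L
    if (verbose)
      message("running ", n_chains, " chain(s) x ",
              spec$mcmc$burn_in + spec$mcmc$iterations, " sweeps")
    chains <- run_chains(ctx, spec$mcmc$burn_in, spec$mcmc$iterations,
                         spec$mcmc$thin, seeds)
  }
  summ <- summarize_draws(chains)
  structure(list(chains = chains, summary = summ, ctx = ctx, spec = spec,
                 selection = selection, prior_only = prior_only,
                 call = cl),
            class = "phthalmix_fit")
}

# i.i.d. draws from the priors packaged like a chain set (prior-only mode)
prior_chain_set <- function(ctx, spec) {
  n <- spec$mcmc$iterations
  set.seed(spec$mcmc$seed)
  pn <- colnames(ctx$X)
  draws <- vapply(seq_along(pn), function(j)
    stats::rnorm(n, 0, sqrt(1 / ctx$col_info$prior_prec[j])),
    numeric(n))
  colnames(draws) <- pn
  vp <- spec$variance_prior
  draws <- cbind(draws,
                 sigma_e = sqrt(1 / stats::rgamma(n, vp$a, vp$b)),
                 sigma_b = sqrt(1 / stats::rgamma(n, vp$a, vp$b)))
  if (spec$missingness == "MNAR") {
    gn <- c(colnames(ctx$Z_sel), "y")
    g <- vapply(gn, function(nm)
      stats::rnorm(n, 0, sqrt(1 / ctx$sel_prior_prec[nm])), numeric(n))
    colnames(g) <- paste0("gamma_", gn)
    draws <- cbind(draws, g)
  }
  structure(list(draws = list(draws), accept = list(NULL),
                 states = list(NULL), burn_in = 0L, iterations = n,
                 seeds = spec$mcmc$seed),
            class = "chain_set")
}

#' Fit the loss-to-follow-up selection model
#'
#' Convenience wrapper: fits the outcome model jointly with the logistic
#' missingness model over all children with measured exposures, and
#' reports the odds ratio of missingness per 1% fat mass.
#'
#' @param mothers,visits Full-cohort data (visit rows present, or
#'   synthesized at schedule ages, for unobserved visits).
#' @param spec Outcome \code{\link{model_spec}} (its \code{missingness} is
#'   forced to \code{"MNAR"}).
#' @param selection A \code{\link{selection_spec}}.
#' @param registry Metabolite registry.
#' @param ... Passed to \code{\link{phthalmix_fit}}.
#' @return A \code{"phthalmix_fit"}; see also \code{\link{dropout_or}}.
#' @export
fit_selection <- function(mothers, visits, spec = model_spec(),
                          selection = selection_spec(),
                          registry = default_registry(), ...) {
  spec$missingness <- "MNAR"
  if (all(is.na(percent_fat_mass(visits$fat_mass, visits$weight))))
    stop("fit_selection: all outcomes are missing")
  phthalmix_fit(mothers, visits, spec, registry, selection, ...)
}

#' Odds ratio for outcome missingness per 1% fat mass
#'
#' @param object An MNAR \code{"phthalmix_fit"}.
#' @return Named vector: posterior mean OR and 95% CI bounds for
#'   \eqn{\exp(\gamma_y)}.
#' @export
dropout_or <- function(object) {
  stopifnot(inherits(object, "phthalmix_fit"))
  d <- do.call(rbind, object$chains$draws)
  if (!"gamma_y" %in% colnames(d))
    stop("dropout_or: not a selection-model fit")
  or <- exp(d[, "gamma_y"])
  c(or = mean(or),
    ci95_lower = unname(stats::quantile(or, 0.025)),
    ci95_upper = unname(stats::quantile(or, 0.975)))
}

#' Continue a fitted model's first chain from its checkpoint
#'
#' Resumes the stored sampler state and RNG stream, reproducing exactly
#' the draws an uninterrupted longer run would have produced.
#'
#' @param object A \code{"phthalmix_fit"} (posterior fits only).
#' @param iterations Additional post-burn-in iterations.
#' @return List with the additional \code{draws} matrix and the updated
#'   states.
#' @export
resume_fit <- function(object, iterations) {
  stopifnot(inherits(object, "phthalmix_fit"), !object$prior_only)
  res <- lapply(seq_along(object$chains$states), function(i)
    run_mcmc(object$ctx, burn_in = 0L, iterations = iterations,
             thin = object$spec$mcmc$thin,
             init = object$chains$states[[i]],
             rng = object$chains$rng[[i]]))
  list(draws = lapply(res, `[[`, "draws"),
       states = lapply(res, `[[`, "state"))
}

# --- methods ----------------------------------------------------------------

#' @export
print.phthalmix_fit <- function(x, ...) {
  s <- x$spec
  cat("Bayesian phthalate-mixture fat-mass model",
      if (x$prior_only) "(prior only)" else "", "\n")
  cat("  exposures: ", paste(s$exposures, collapse = ", "),
      " [", s$exposure_coding, " coding]\n", sep = "")
  cat("  interaction:", s$interaction, "  missingness:", s$missingness, "\n")
  cat("  children:", x$ctx$n_child, "  modeled visit rows:", x$ctx$N,
      " (", sum(x$ctx$obs), "observed )\n")
  cat("  chains:", length(x$chains$draws), " retained draws/chain:",
      nrow(x$chains$draws[[1]]), "\n\n")
  expo <- x$summary[x$summary$parameter %in% x$ctx$col_info$exposure, ]
  cat("Exposure effects (per SD ln concentration or tertile contrast):\n")
  print(data.frame(parameter = expo$parameter,
                   estimate = round(expo$mean, 2),
                   ci95 = sprintf("(%.2f, %.2f)", expo$ci95_lower,
                                  expo$ci95_upper)),
        row.names = FALSE)
  if (s$missingness == "MNAR" && !x$prior_only) {
    or <- dropout_or(x)
    cat(sprintf("\nOR for missingness per 1%% fat mass: %.2f (%.2f, %.2f)\n",
                or[1], or[2], or[3]))
  }
  invisible(x)
}

#' @export
summary.phthalmix_fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.phthalmix_fit", "data.frame")
  out
}

#' @export
print.summary.phthalmix_fit <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.phthalmix_fit <- function(object, ...) {
  pn <- colnames(object$ctx$X)
  stats::setNames(object$summary$mean[match(pn, object$summary$parameter)],
                  pn)
}

#' @export
fitted.phthalmix_fit <- function(object, include_random = TRUE, ...) {
  ctx <- object$ctx
  beta <- coef(object)
  mu <- as.numeric(ctx$X %*% beta)
  if (include_random && !object$prior_only) {
    bmat <- vapply(object$chains$states, function(st) st$b,
                   numeric(ctx$n_child))
    mu <- mu + rowMeans(bmat)[ctx$row_child]
  }
  mu
}

#' @export
predict.phthalmix_fit <- function(object, newdata = NULL,
                                  include_random = TRUE, ...) {
  if (is.null(newdata)) return(fitted(object, include_random))
  # new children: population-level prediction at the frozen constants
  ctx2 <- prepare_model_data(newdata$mothers, newdata$visits, object$spec,
                             object$ctx$registry, object$selection)
  beta <- coef(object)
  common <- intersect(colnames(ctx2$X), names(beta))
  as.numeric(ctx2$X[, common, drop = FALSE] %*% beta[common])
}

#' @export
residuals.phthalmix_fit <- function(object, ...) {
  ctx <- object$ctx
  (ctx$y - fitted(object))[ctx$obs]
}

#' @export
simulate.phthalmix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- do.call(rbind, object$chains$draws)
  ctx <- object$ctx
  pn <- colnames(ctx$X)
  out <- matrix(NA_real_, ctx$N, nsim)
  idx <- sample.int(nrow(d), nsim, replace = TRUE)
  for (s in seq_len(nsim)) {
    beta <- d[idx[s], pn]
    sig_e <- d[idx[s], "sigma_e"]
    sig_b <- d[idx[s], "sigma_b"]
    b <- stats::rnorm(ctx$n_child, 0, sig_b)
    out[, s] <- as.numeric(ctx$X %*% beta) + b[ctx$row_child] +
      stats::rnorm(ctx$N, 0, sig_e)
  }
  as.data.frame(out)
}

#' @export
plot.phthalmix_fit <- function(x, type = c("forest", "trace"),
                               parameters = NULL, ...) {
  type <- match.arg(type)
  if (type == "forest") {
    expo <- x$summary[x$summary$parameter %in% x$ctx$col_info$exposure, ]
    k <- nrow(expo)
    graphics::plot(expo$mean, seq_len(k), xlim = range(expo$ci95_lower,
                                                       expo$ci95_upper, 0),
                   ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                   xlab = "Difference in percent fat mass", ylab = "",
                   main = "Exposure effects (95% CrI)", ...)
    graphics::segments(expo$ci95_lower, seq_len(k), expo$ci95_upper,
                       seq_len(k))
    graphics::abline(v = 0, lty = 2, col = "grey50")
    graphics::axis(2, at = seq_len(k), labels = expo$parameter, las = 1)
  } else {
    pars <- parameters %||% utils::head(x$ctx$col_info$exposure, 4)
    old <- graphics::par(mfrow = c(length(pars), 1),
                         mar = c(2, 4, 1.5, 1))
    on.exit(graphics::par(old))
    for (p in pars) {
      graphics::plot(NULL, xlim = c(1, nrow(x$chains$draws[[1]])),
                     ylim = range(vapply(x$chains$draws,
                                         function(d) range(d[, p]),
                                         numeric(2))),
                     xlab = "", ylab = p, main = "")
      for (ci in seq_along(x$chains$draws))
        graphics::lines(x$chains$draws[[ci]][, p], col = ci)
    }
  }
  invisible(x)
}
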
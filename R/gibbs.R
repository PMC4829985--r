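# Gibbs sampler for the joint model: conjugate block updates for the fixed
# effects, random intercepts and variances; truncated-normal re-imputation
# of below-LOD concentrations with per-sweep DEHP molar-sum recomputation;
# Metropolis / exact-Bernoulli updates for the covariate-imputation
# submodels; and, under MNAR, joint updates of the missing outcomes and the
# selection coefficients.
#
# The sampler state is an environment (mutated in place); every update
# conditions on the current values of everything else, so the scan leaves
# the joint posterior invariant component by component.

#' Initialize the sampler state
#'
#' @param ctx Model context from \code{\link{prepare_model_data}}.
#' @return An environment holding the full parameter state.
#' @export
init_state <- function(ctx) {
  st <- new.env(parent = emptyenv())
  p <- ncol(ctx$X)
  st$X <- ctx$X
  st$ln_conc <- ctx$ln_conc0
  st$gwg_ratio <- ctx$gwg_ratio0
  cc <- ctx$cov_const
  st$gwg_ratio[is.na(st$gwg_ratio)] <- cc$gwg_ratio["mu"]
  st$W <- ctx$mothers$last_preg_weight
  st$W[is.na(st$W)] <- cc$last_preg_weight["mu"]
  bf <- ctx$mothers$breastfed
  bf[is.na(bf)] <- round(mean(bf, na.rm = TRUE))
  st$B <- bf
  act <- ctx$visits$active
  act[is.na(act)] <- round(mean(act, na.rm = TRUE))
  st$A <- act

  st$y <- ctx$y
  yobs <- ctx$y[ctx$obs]
  # least-squares warm start for the fixed effects
  st$beta <- tryCatch({
    cf <- stats::lm.fit(ctx$X[ctx$obs, , drop = FALSE], yobs)$coefficients
    cf[!is.finite(cf)] <- 0
    as.numeric(cf)
  }, error = function(e) rep(0, p))
  names(st$beta) <- colnames(ctx$X)
  st$b <- rep(0, ctx$n_child)
  vy <- stats::var(yobs)
  st$sig2_e <- vy / 2
  st$sig2_b <- if (!is.null(ctx$spec$sigma_b_fixed))
    ctx$spec$sigma_b_fixed^2 else vy / 4

  # submodel coefficients (warm starts from classical fits)
  Wstd <- (st$W - cc$last_preg_weight["mu"]) / cc$last_preg_weight["sd"]
  fitW <- stats::lm.fit(ctx$Z_W, Wstd)
  st$theta_W <- ifelse(is.finite(fitW$coefficients), fitW$coefficients, 0)
  st$sig2_W <- max(stats::var(fitW$residuals), 1e-4)
  st$theta_B <- glm_warm_start(ctx$Z_B, st$B)
  st$theta_A <- glm_warm_start(ctx$Z_A, st$A)
  st$u <- rep(0, ctx$n_child)
  st$sig2_u <- 1
  # block Metropolis proposal factors (frozen: tuning does not adapt after
  # burn-in, preserving the stationary distribution)
  st$prop_B <- mh_proposal_chol(ctx$Z_B, st$B, NULL)
  st$prop_A <- mh_proposal_chol(ctx$Z_A, st$A, NULL)
  st$acc <- c(W = 0, theta_B = 0, theta_A = 0, u = 0, gamma = 0, y_mis = 0)
  st$n_sweeps <- 0L

  if (ctx$spec$missingness == "MNAR") {
    mu_mis <- as.numeric(ctx$X[ctx$mis_idx, , drop = FALSE] %*% st$beta)
    st$y[ctx$mis_idx] <- mu_mis
    st$Z_sel <- ctx$Z_sel
    M <- as.numeric(!ctx$obs)
    Zy <- cbind(ctx$Z_sel, y = st$y)
    st$gamma <- glm_warm_start(Zy, M)
    names(st$gamma) <- colnames(Zy)
    if (!is.null(ctx$selection$fix_gamma_y))
      st$gamma["y"] <- ctx$selection$fix_gamma_y
    st$prop_gamma <- mh_proposal_chol(Zy, M, NULL)
  }
  st
}

glm_warm_start <- function(Z, yb) {
  cf <- tryCatch(
    suppressWarnings(stats::glm.fit(Z, yb,
                                    family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(Z)))
  cf[!is.finite(cf)] <- 0
  pmin(pmax(as.numeric(cf), -5), 5)
}

# scaled Cholesky of an approximate posterior covariance for block RW-MH
mh_proposal_chol <- function(Z, yb, w) {
  p <- ncol(Z)
  V <- tryCatch({
    pr <- pmin(pmax(inv_logit(as.numeric(Z %*% glm_warm_start(Z, yb))),
                    0.05), 0.95)
    info <- crossprod(Z * (pr * (1 - pr)), Z) + diag(p)
    solve(info)
  }, error = function(e) diag(p) * 0.01)
  t(chol(V * 2.4^2 / p))
}

bernoulli_loglik <- function(eta, yb) {
  sum(yb * eta - log1p(exp(eta)))
}

# refresh the exposure columns of X from the current log concentrations
# (one block assignment: column updates copy the whole matrix, so batch them)
refresh_exposure_cols <- function(st, ctx) {
  if (ctx$spec$exposure_coding != "continuous") return(invisible())
  E <- exposure_scores(ctx, st$ln_conc)
  rc <- ctx$row_child
  block <- E[rc, ctx$spec$exposures, drop = FALSE]
  cols <- ctx$spec$exposures
  if (ctx$spec$interaction == "sex") {
    block <- cbind(block, block * ctx$sex_row)
    cols <- c(cols, paste0("sex:", ctx$spec$exposures))
  }
  st$X[, cols] <- block
  invisible()
}

#' Re-impute below-LOD log concentrations
#'
#' Each censored cell is redrawn from a normal with the frozen mean and SD
#' of that metabolite's observed (above-LOD) log distribution, truncated
#' above at the log of the corrected LOD; the DEHP molar sum is then
#' recomputed from the component values and restandardized with the frozen
#' constants.
#'
#' @param state Sampler state (environment), mutated in place.
#' @param ctx Model context.
#' @return The state, invisibly.
#' @export
impute_censored <- function(state, ctx) {
  if (!length(ctx$cens_info)) return(invisible(state))
  for (code in names(ctx$cens_info)) {
    ci <- ctx$cens_info[[code]]
    state$ln_conc[ci$idx, code] <-
      rtnorm_upper(length(ci$idx), ci$mu, ci$sd, ci$bound)
  }
  refresh_exposure_cols(state, ctx)
  invisible(state)
}

# update the GWG polynomial columns of X (and the dynamic submodel /
# selection columns) for the given mothers, in one block assignment
refresh_gwg_cols <- function(st, ctx, mothers_idx) {
  if (!length(mothers_idx)) return(invisible())
  cc <- ctx$cov_const
  g <- std2(st$gwg_ratio[mothers_idx], cc$gwg_ratio["mu"],
            cc$gwg_ratio["sd"])
  lens <- lengths(ctx$rows_of_child[mothers_idx])
  rows <- unlist(ctx$rows_of_child[mothers_idx], use.names = FALSE)
  grow <- rep(g, lens)
  ndeg <- length(ctx$col_info$gwg)
  block <- vapply(seq_len(ndeg), function(d) grow^d, numeric(length(rows)))
  st$X[rows, ctx$col_info$gwg] <- block
  if (!is.null(st$Z_sel) && length(ctx$Z_sel_gwg_col))
    st$Z_sel[rows, ctx$Z_sel_gwg_col] <- grow
  invisible()
}

current_Z_B <- function(st, ctx) {
  Z <- ctx$Z_B
  cc <- ctx$cov_const
  Z[, ctx$Z_B_gwg_col] <- std2(st$gwg_ratio, cc$gwg_ratio["mu"],
                               cc$gwg_ratio["sd"])
  Z
}

#' One full update of the imputed covariates
#'
#' Missing last pregnancy weights are updated by Metropolis steps whose
#' independence proposal is the normal imputation submodel, accepted
#' against the outcome likelihood (gestational weight-gain adequacy is
#' recomputed from the proposed weight); missing breastfeeding and
#' physical-activity indicators are drawn from their exact Bernoulli full
#' conditionals, which combine the logistic submodel with the outcome
#' likelihood.
#'
#' @param state Sampler state (environment), mutated in place.
#' @param ctx Model context.
#' @return The state, invisibly.
#' @export
impute_covariates <- function(state, ctx) {
  st <- state
  cc <- ctx$cov_const
  se <- sqrt(st$sig2_e)
  beta <- st$beta
  gwg_cols <- ctx$col_info$gwg
  beta_gwg <- beta[gwg_cols]
  sel <- !is.null(st$Z_sel)

  # --- last pregnancy weight (normal submodel; MH with outcome feedback).
  # The proposal is the imputation submodel itself, so the acceptance ratio
  # reduces to the outcome (and dependent-submodel) likelihood ratio.
  # Mothers' visit rows are disjoint, so all steps run vectorized.
  if (length(ctx$W_missing)) {
    mi <- ctx$W_missing
    K <- length(mi)
    muW <- cc$last_preg_weight["mu"]; sdW <- cc$last_preg_weight["sd"]
    w_std_prop <- stats::rnorm(K, as.numeric(ctx$Z_W[mi, , drop = FALSE] %*%
                                               st$theta_W),
                               sqrt(st$sig2_W))
    W_prop <- muW + sdW * w_std_prop
    ratio_prop <- 100 * (W_prop - ctx$prepreg_weight[mi]) /
      ctx$expected_gain[mi]
    g_old <- std2(st$gwg_ratio[mi], cc$gwg_ratio["mu"], cc$gwg_ratio["sd"])
    g_new <- std2(ratio_prop, cc$gwg_ratio["mu"], cc$gwg_ratio["sd"])
    degs <- seq_along(gwg_cols)
    dmean <- as.numeric((outer(g_new, degs, `^`) -
                           outer(g_old, degs, `^`)) %*% beta_gwg)
    lens <- lengths(ctx$rows_of_child[mi])
    rows <- unlist(ctx$rows_of_child[mi], use.names = FALSE)
    child_of_row <- rep(seq_len(K), lens)
    mu_old <- as.numeric(st$X[rows, , drop = FALSE] %*% beta) +
      st$b[mi][child_of_row]
    yr <- st$y[rows]
    use <- if (ctx$spec$missingness == "MNAR") rep(TRUE, length(rows))
           else ctx$obs[rows]
    drow <- (-(yr - mu_old - dmean[child_of_row])^2 + (yr - mu_old)^2) /
      (2 * st$sig2_e)
    drow[!use] <- 0
    lr <- as.numeric(rowsum(drow, child_of_row, reorder = TRUE))
    # breastfed submodel conditions on GWG adequacy
    th_g <- st$theta_B[ctx$Z_B_gwg_col]
    eta_base <- as.numeric(ctx$Z_B[mi, , drop = FALSE] %*% st$theta_B) -
      th_g * ctx$Z_B[mi, ctx$Z_B_gwg_col]
    eta_old <- eta_base + th_g * g_old
    eta_new <- eta_base + th_g * g_new
    lr <- lr + st$B[mi] * (eta_new - eta_old) -
      log1p(exp(eta_new)) + log1p(exp(eta_old))
    if (sel && length(ctx$Z_sel_gwg_col)) {
      eta_s_old <- as.numeric(st$Z_sel[rows, , drop = FALSE] %*%
                                st$gamma[colnames(st$Z_sel)]) +
        st$gamma["y"] * yr
      g_sel <- st$gamma[colnames(st$Z_sel)[ctx$Z_sel_gwg_col]]
      eta_s_new <- eta_s_old + g_sel * (g_new - g_old)[child_of_row]
      M <- as.numeric(!ctx$obs[rows])
      dsel <- M * (eta_s_new - eta_s_old) - log1p(exp(eta_s_new)) +
        log1p(exp(eta_s_old))
      lr <- lr + as.numeric(rowsum(dsel, child_of_row, reorder = TRUE))
    }
    acc <- log(stats::runif(K)) < lr
    if (any(acc)) {
      st$W[mi[acc]] <- W_prop[acc]
      st$gwg_ratio[mi[acc]] <- ratio_prop[acc]
      refresh_gwg_cols(st, ctx, mi[acc])
    }
    st$acc["W"] <- st$acc["W"] + mean(acc)
  }

  # --- breastfed (exact Bernoulli full conditional)
  if (length(ctx$B_missing)) {
    Z_B <- current_Z_B(st, ctx)
    bcol <- "breastfed"
    bb <- beta[bcol]
    for (i in ctx$B_missing) {
      rows <- ctx$rows_of_child[[i]]
      use <- if (ctx$spec$missingness == "MNAR") rep(TRUE, length(rows))
             else ctx$obs[rows]
      mu_base <- as.numeric(st$X[rows, , drop = FALSE] %*% beta) + st$b[i] -
        bb * st$B[i]
      yr <- st$y[rows]
      ll1 <- sum((-(yr - mu_base - bb)^2)[use]) / (2 * st$sig2_e)
      ll0 <- sum((-(yr - mu_base)^2)[use]) / (2 * st$sig2_e)
      lo <- sum(Z_B[i, ] * st$theta_B) + ll1 - ll0
      if (sel && length(ctx$Z_sel_bf_col)) {
        M <- as.numeric(!ctx$obs[rows])
        eta0 <- as.numeric(st$Z_sel[rows, , drop = FALSE] %*%
                             st$gamma[colnames(st$Z_sel)]) +
          st$gamma["y"] * yr -
          st$gamma[colnames(st$Z_sel)[ctx$Z_sel_bf_col]] * st$B[i]
        g_bf <- st$gamma[colnames(st$Z_sel)[ctx$Z_sel_bf_col]]
        lo <- lo + sum(M * g_bf - log1p(exp(eta0 + g_bf)) +
                         log1p(exp(eta0)))
      }
      newB <- stats::rbinom(1, 1, inv_logit(lo))
      if (newB != st$B[i]) {
        st$B[i] <- newB
        st$X[rows, bcol] <- newB
        if (sel && length(ctx$Z_sel_bf_col))
          st$Z_sel[rows, ctx$Z_sel_bf_col] <- newB
      }
    }
  }

  # --- physical activity (row-level exact Bernoulli full conditional)
  if (length(ctx$A_missing)) {
    r <- ctx$A_missing
    ba <- beta["active"]
    rc <- ctx$row_child[r]
    mu_base <- as.numeric(st$X[r, , drop = FALSE] %*% beta) + st$b[rc] -
      ba * st$A[r]
    yr <- st$y[r]
    use <- if (ctx$spec$missingness == "MNAR") rep(TRUE, length(r))
           else ctx$obs[r]
    dll <- ((-(yr - mu_base - ba)^2 + (yr - mu_base)^2) / (2 * st$sig2_e))
    dll[!use] <- 0
    lo <- as.numeric(ctx$Z_A[r, , drop = FALSE] %*% st$theta_A) +
      st$u[rc] + dll
    newA <- stats::rbinom(length(r), 1, inv_logit(lo))
    chg <- newA != st$A[r]
    if (any(chg)) {
      st$A[r[chg]] <- newA[chg]
      st$X[r[chg], "active"] <- newA[chg]
    }
  }
  invisible(st)
}

# conjugate update of the imputation submodel for last pregnancy weight
update_theta_W <- function(st, ctx) {
  cc <- ctx$cov_const
  Wstd <- (st$W - cc$last_preg_weight["mu"]) / cc$last_preg_weight["sd"]
  Z <- ctx$Z_W
  p <- ncol(Z)
  ZtZ <- ctx$ZtZ_W %||% crossprod(Z)    # Z_W is static
  prec <- ZtZ / st$sig2_W + diag(ctx$spec$tau_imputation, p)
  U <- chol(prec)
  m <- backsolve(U, backsolve(U, crossprod(Z, Wstd) / st$sig2_W,
                              transpose = TRUE))
  st$theta_W <- as.numeric(m + backsolve(U, stats::rnorm(p)))
  names(st$theta_W) <- colnames(Z)
  resid <- Wstd - as.numeric(Z %*% st$theta_W)
  vp <- ctx$spec$variance_prior
  st$sig2_W <- 1 / stats::rgamma(1, vp$a + length(Wstd) / 2,
                                 vp$b + sum(resid^2) / 2)
  invisible(st)
}

update_theta_B <- function(st, ctx) {
  Z <- current_Z_B(st, ctx)
  tau <- ctx$spec$tau_imputation
  cur <- st$theta_B
  prop <- cur + as.numeric(st$prop_B %*% stats::rnorm(length(cur)))
  ll_cur <- bernoulli_loglik(as.numeric(Z %*% cur), st$B) -
    tau * sum(cur^2) / 2
  ll_prop <- bernoulli_loglik(as.numeric(Z %*% prop), st$B) -
    tau * sum(prop^2) / 2
  if (log(stats::runif(1)) < ll_prop - ll_cur) {
    st$theta_B <- prop
    names(st$theta_B) <- colnames(Z)
    st$acc["theta_B"] <- st$acc["theta_B"] + 1
  }
  invisible(st)
}

update_theta_A <- function(st, ctx) {
  Z <- ctx$Z_A
  tau <- ctx$spec$tau_imputation
  rc <- ctx$row_child
  cur <- st$theta_A
  prop <- cur + as.numeric(st$prop_A %*% stats::rnorm(length(cur)))
  ll_cur <- bernoulli_loglik(as.numeric(Z %*% cur) + st$u[rc], st$A) -
    tau * sum(cur^2) / 2
  ll_prop <- bernoulli_loglik(as.numeric(Z %*% prop) + st$u[rc], st$A) -
    tau * sum(prop^2) / 2
  if (log(stats::runif(1)) < ll_prop - ll_cur) {
    st$theta_A <- prop
    names(st$theta_A) <- colnames(Z)
    st$acc["theta_A"] <- st$acc["theta_A"] + 1
  }
  # random intercepts: per-child random-walk MH (vectorized)
  rc_eta <- as.numeric(Z %*% st$theta_A)
  u_prop <- st$u + stats::rnorm(ctx$n_child, 0, 0.5)
  eta_cur <- rc_eta + st$u[rc]
  eta_prop <- rc_eta + u_prop[rc]
  d_row <- st$A * (eta_prop - eta_cur) - log1p(exp(eta_prop)) +
    log1p(exp(eta_cur))
  d_child <- as.numeric(rowsum(d_row, rc, reorder = TRUE)) +
    (st$u^2 - u_prop^2) / (2 * st$sig2_u)
  acc <- log(stats::runif(ctx$n_child)) < d_child
  st$u[acc] <- u_prop[acc]
  st$acc["u"] <- st$acc["u"] + mean(acc)
  vp <- ctx$spec$variance_prior
  st$sig2_u <- 1 / stats::rgamma(1, vp$a + ctx$n_child / 2,
                                 vp$b + sum(st$u^2) / 2)
  invisible(st)
}

update_beta <- function(st, ctx) {
  X <- st$X
  prec0 <- ctx$col_info$prior_prec
  resid_target <- st$y - st$b[ctx$row_child]
  prec <- crossprod(X) / st$sig2_e + diag(prec0, ncol(X))
  U <- chol(prec)
  m <- backsolve(U, backsolve(U, crossprod(X, resid_target) / st$sig2_e,
                              transpose = TRUE))
  st$beta <- as.numeric(m + backsolve(U, stats::rnorm(ncol(X))))
  names(st$beta) <- colnames(X)
  invisible(st)
}

update_b <- function(st, ctx) {
  if (!is.null(ctx$spec$sigma_b_fixed) && ctx$spec$sigma_b_fixed == 0) {
    st$b <- rep(0, ctx$n_child)
    return(invisible(st))
  }
  resid <- st$y - as.numeric(st$X %*% st$beta)
  sums <- as.numeric(rowsum(resid, ctx$row_child, reorder = TRUE))
  ni <- tabulate(ctx$row_child, ctx$n_child)
  prec_i <- ni / st$sig2_e + 1 / st$sig2_b
  st$b <- stats::rnorm(ctx$n_child, (sums / st$sig2_e) / prec_i,
                       sqrt(1 / prec_i))
  invisible(st)
}

update_variances <- function(st, ctx) {
  vp <- ctx$spec$variance_prior
  resid <- st$y - as.numeric(st$X %*% st$beta) - st$b[ctx$row_child]
  st$sig2_e <- 1 / stats::rgamma(1, vp$a + ctx$N / 2,
                                 vp$b + sum(resid^2) / 2)
  if (is.null(ctx$spec$sigma_b_fixed)) {
    st$sig2_b <- 1 / stats::rgamma(1, vp$a + ctx$n_child / 2,
                                   vp$b + sum(st$b^2) / 2)
  } else {
    st$sig2_b <- ctx$spec$sigma_b_fixed^2
  }
  invisible(st)
}

# --- selection-model components (MNAR) --------------------------------------

selection_eta <- function(st, y = st$y) {
  as.numeric(st$Z_sel %*% st$gamma[colnames(st$Z_sel)]) + st$gamma["y"] * y
}

update_y_mis <- function(st, ctx) {
  idx <- ctx$mis_idx
  if (!length(idx)) return(invisible(st))
  mu <- as.numeric(st$X[idx, , drop = FALSE] %*% st$beta) +
    st$b[ctx$row_child[idx]]
  y_prop <- stats::rnorm(length(idx), mu, sqrt(st$sig2_e))
  eta_base <- as.numeric(st$Z_sel[idx, , drop = FALSE] %*%
                           st$gamma[colnames(st$Z_sel)])
  # rows are missing (M = 1): tilt is the logistic success probability
  d <- stats::plogis(eta_base + st$gamma["y"] * y_prop, log.p = TRUE) -
    stats::plogis(eta_base + st$gamma["y"] * st$y[idx], log.p = TRUE)
  acc <- log(stats::runif(length(idx))) < d
  st$y[idx[acc]] <- y_prop[acc]
  st$acc["y_mis"] <- st$acc["y_mis"] + mean(acc)
  invisible(st)
}

update_gamma <- function(st, ctx) {
  prec <- ctx$sel_prior_prec
  M <- as.numeric(!ctx$obs)
  cur <- st$gamma
  prop <- cur + as.numeric(st$prop_gamma %*% stats::rnorm(length(cur)))
  if (!is.null(ctx$selection$fix_gamma_y))
    prop["y"] <- ctx$selection$fix_gamma_y
  eta_cur <- selection_eta(st)
  st_gamma_save <- st$gamma
  st$gamma <- prop
  eta_prop <- selection_eta(st)
  st$gamma <- st_gamma_save
  ll_cur <- bernoulli_loglik(eta_cur, M) - sum(prec * cur^2) / 2
  ll_prop <- bernoulli_loglik(eta_prop, M) - sum(prec * prop^2) / 2
  if (log(stats::runif(1)) < ll_prop - ll_cur) {
    st$gamma <- prop
    st$acc["gamma"] <- st$acc["gamma"] + 1
  }
  invisible(st)
}

#' One full Gibbs sweep
#'
#' Updates, in order: below-LOD imputations (with DEHP molar-sum
#' recomputation), imputed covariates, imputation-submodel coefficients,
#' the missing outcomes and selection coefficients (MNAR only), the fixed
#' effects (conjugate normal block), random intercepts (conjugate), and
#' variances (conjugate inverse-gamma).
#'
#' @param state Sampler state (environment), mutated in place.
#' @param ctx Model context.
#' @return The state, invisibly.
#' @export
gibbs_sweep <- function(state, ctx) {
  impute_censored(state, ctx)
  impute_covariates(state, ctx)
  update_theta_W(state, ctx)
  update_theta_B(state, ctx)
  update_theta_A(state, ctx)
  if (ctx$spec$missingness == "MNAR") {
    # extra inner iterations: the selection coefficients and the imputed
    # outcomes are strongly coupled, and these updates are cheap relative
    # to the conjugate blocks
    for (r in 1:2) {
      update_y_mis(state, ctx)
      for (q in 1:5) update_gamma(state, ctx)
    }
  }
  update_beta(state, ctx)
  update_b(state, ctx)
  update_variances(state, ctx)
  state$n_sweeps <- state$n_sweeps + 1L
  invisible(state)
}

#' Log joint density of the current state (up to a constant)
#'
#' Sums the Gaussian outcome likelihood, the random-intercept and
#' coefficient priors, the truncated-lognormal terms for censored
#' concentrations, the covariate-imputation submodel likelihoods and
#' priors, the variance priors and, under MNAR, the missingness likelihood
#' and selection priors.  Support violations (a censored log concentration
#' above its bound) yield \code{-Inf}; any other non-finite component is an
#' error naming the component.
#'
#' @param state Sampler state.
#' @param ctx Model context.
#' @return Scalar log density (up to an additive constant).
#' @export
log_joint <- function(state, ctx) {
  st <- state
  comp <- c()
  mu <- as.numeric(st$X %*% st$beta) + st$b[ctx$row_child]
  use <- if (ctx$spec$missingness == "MNAR") rep(TRUE, ctx$N) else ctx$obs
  comp["outcome"] <- sum(stats::dnorm(st$y[use], mu[use],
                                      sqrt(st$sig2_e), log = TRUE))
  if (is.null(ctx$spec$sigma_b_fixed) || ctx$spec$sigma_b_fixed > 0)
    comp["random_intercepts"] <- sum(stats::dnorm(st$b, 0,
                                                  sqrt(st$sig2_b),
                                                  log = TRUE))
  comp["beta_prior"] <- sum(stats::dnorm(st$beta, 0,
                                         sqrt(1 / ctx$col_info$prior_prec),
                                         log = TRUE))
  if (length(ctx$cens_info)) {
    v <- 0
    for (code in names(ctx$cens_info)) {
      ci <- ctx$cens_info[[code]]
      v <- v + sum(dtnorm_upper_log(st$ln_conc[ci$idx, code], ci$mu, ci$sd,
                                    ci$bound))
    }
    comp["censored_imputation"] <- v
  }
  cc <- ctx$cov_const
  Wstd <- (st$W - cc$last_preg_weight["mu"]) / cc$last_preg_weight["sd"]
  comp["submodel_W"] <- sum(stats::dnorm(Wstd,
                                         as.numeric(ctx$Z_W %*% st$theta_W),
                                         sqrt(st$sig2_W), log = TRUE))
  etaB <- as.numeric(current_Z_B(st, ctx) %*% st$theta_B)
  comp["submodel_B"] <- sum(st$B * etaB - log1p(exp(etaB)))
  etaA <- as.numeric(ctx$Z_A %*% st$theta_A) + st$u[ctx$row_child]
  comp["submodel_A"] <- sum(st$A * etaA - log1p(exp(etaA))) +
    sum(stats::dnorm(st$u, 0, sqrt(st$sig2_u), log = TRUE))
  tau_i <- ctx$spec$tau_imputation
  comp["theta_priors"] <- sum(stats::dnorm(c(st$theta_W, st$theta_B,
                                             st$theta_A),
                                           0, sqrt(1 / tau_i), log = TRUE))
  vp <- ctx$spec$variance_prior
  ig <- function(x) vp$a * log(vp$b) - lgamma(vp$a) -
    (vp$a + 1) * log(x) - vp$b / x
  vr <- ig(st$sig2_e) + ig(st$sig2_W) + ig(st$sig2_u)
  if (is.null(ctx$spec$sigma_b_fixed)) vr <- vr + ig(st$sig2_b)
  comp["variance_priors"] <- vr
  if (ctx$spec$missingness == "MNAR") {
    M <- as.numeric(!ctx$obs)
    eta <- selection_eta(st)
    comp["selection"] <- sum(M * eta - log1p(exp(eta))) +
      sum(stats::dnorm(st$gamma, 0,
                       sqrt(1 / ctx$sel_prior_prec[names(st$gamma)]),
                       log = TRUE))
  }
  bad <- names(comp)[is.nan(comp) | is.na(comp)]
  if (length(bad))
    stop("log_joint: non-finite component(s): ", paste(bad, collapse = ", "))
  sum(comp)
}
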
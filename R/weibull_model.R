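#' Prior specification for the Weibull regression model
#'
#' Independent priors: `alpha ~ Gamma(u_alpha, v_alpha)` (shape/rate) and
#' `beta_j ~ N(0, sigma2)` with a common variance (diagonal prior
#' covariance).  Diffuse defaults: small Gamma hyperparameters and a large
#' `sigma2`.
#'
#' @param u_alpha,v_alpha positive Gamma shape and rate for `alpha`.
#' @param sigma2 positive common prior variance for every regression
#'   coefficient (intercept included).
#' @return object of class `weibull_prior`.
#' @export
weibull_prior <- function(u_alpha = 0.01, v_alpha = 0.01, sigma2 = 100) {
  if (u_alpha <= 0 || v_alpha <= 0 || sigma2 <= 0) {
    stop("all prior hyperparameters must be positive")
  }
  structure(list(u_alpha = u_alpha, v_alpha = v_alpha, sigma2 = sigma2),
            class = "weibull_prior")
}

#' Linear predictor for the log-scale
#'
#' Covariates enter the Weibull model through the log-scale
#' `lambda_i`.  The default `"identity"` link sets `lambda_i = x_i' beta`
#' (lambda is real-valued, so no constraint is needed); the alternative
#' `"exp"` link sets `lambda_i = exp(x_i' beta)`, forcing a positive
#' log-scale.
#'
#' @param x covariate vector or matrix (rows = subjects), intercept first.
#' @param beta coefficient vector of matching length.
#' @param link `"identity"` (default) or `"exp"`.
#' @return `lambda` value(s).
#' @export
linear_predictor <- function(x, beta, link = c("identity", "exp")) {
  link <- match.arg(link)
  if (is.matrix(x)) {
    if (ncol(x) != length(beta)) stop("covariate/coefficient length mismatch")
    eta <- drop(x %*% beta)
  } else {
    if (length(x) != length(beta)) stop("covariate/coefficient length mismatch")
    eta <- sum(x * beta)
  }
  if (link == "exp") exp(eta) else eta
}

#' Weibull regression log-likelihood
#'
#' Right-censored log-likelihood
#' `sum_i delta_i (log alpha + (alpha-1) log t_i + lambda_i) - t_i^alpha
#' exp(lambda_i)` with per-subject `lambda_i = x_i' beta` (or its exp-link
#' variant).  Equals the sum of `weibull_logpdf` over events and
#' `weibull_logsurv` over censored subjects.
#'
#' @param data a [survival_dataset()].
#' @param alpha positive shape.
#' @param beta coefficient vector (length `ncol(data$X)`).
#' @param link see [linear_predictor()].
#' @return log-likelihood value.
#' @export
weibull_loglik <- function(data, alpha, beta, link = "identity") {
  stopifnot(inherits(data, "survival_dataset"))
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be positive")
  lam <- linear_predictor(data$X, beta, link)
  lt <- log(data$time)
  sum(data$status * (log(alpha) + (alpha - 1) * lt + lam) -
        exp(alpha * lt + lam))
}

#' Weibull regression log-prior
#'
#' @param alpha positive shape.
#' @param beta coefficient vector.
#' @param prior a [weibull_prior()].
#' @return log prior density; `-Inf` for `alpha <= 0`.
#' @export
weibull_logprior <- function(alpha, beta, prior = weibull_prior()) {
  stopifnot(inherits(prior, "weibull_prior"))
  if (!is.finite(alpha) || alpha <= 0) return(-Inf)
  stats::dgamma(alpha, shape = prior$u_alpha, rate = prior$v_alpha,
                log = TRUE) +
    sum(stats::dnorm(beta, 0, sqrt(prior$sigma2), log = TRUE))
}

## shared across fitters: crude initial values from the exponential MLE
init_beta0 <- function(data) log(max(1L, event_count(data)) / sum(data$time))

#' Fit the Bayesian Weibull regression model
#'
#' Samples the joint posterior of `(alpha, beta)` by MCMC: `log(alpha)` by
#' univariate slice sampling (the alpha conditional has no closed form) and
#' the coefficient block by adaptive random-walk Metropolis.  The stored
#' chain reports `alpha` on the natural scale; the per-draw log-likelihood
#' is kept for the BIC.
#'
#' @param data a [survival_dataset()] with at least one event.
#' @param prior a [weibull_prior()].
#' @param config a [chain_config()].
#' @param link see [linear_predictor()].
#' @return object of class `survbma_fit` (and `weibull_fit`): list with
#'   `model`, `chain` ([posterior_chain()]), `data`, `prior`, `link`,
#'   `d_s` (parameter count `1 + p + 1`), and internal hooks used by
#'   [max_loglik_estimate()] and [predictive_draws()].
#' @export
fit_weibull <- function(data, prior = weibull_prior(),
                        config = chain_config(), link = "identity") {
  stopifnot(inherits(data, "survival_dataset"))
  if (event_count(data) < 1L) {
    warning("dataset has no events; the likelihood carries no information about alpha")
    stop("refusing to fit a dataset with zero events")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  p1 <- ncol(data$X)
  X <- data$X; tm <- data$time; lt <- log(tm); dl <- data$status
  sdl <- sum(dl); sdllt <- sum(dl * lt); sdb <- sqrt(prior$sigma2)

  ## state: log alpha, beta, cached per-subject lambda = link(X beta);
  ## the alpha slice reuses the cached lambda so each evaluation costs one
  ## exp() pass instead of a full design-matrix product.
  la <- 0; beta <- c(init_beta0(data), rep(0, p1 - 1L))
  lam_of <- function(b) {
    eta <- drop(X %*% b)
    if (link == "exp") exp(eta) else eta
  }
  loglik_state <- function(la, lam, sdllam) {
    a <- exp(la)
    sdl * la + (a - 1) * sdllt + sdllam - sum(exp(a * lt + lam))
  }
  lalpha_prior <- function(v) {
    stats::dgamma(exp(v), prior$u_alpha, rate = prior$v_alpha, log = TRUE) + v
  }
  lbeta_prior <- function(b) sum(stats::dnorm(b, 0, sdb, log = TRUE))
  lam <- lam_of(beta); sdllam <- sum(dl * lam)
  ll <- loglik_state(la, lam, sdllam)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, n_keep, p1 + 1L)
  lp_out <- numeric(n_keep); ll_out <- numeric(n_keep)
  log_sc <- log(rep_len(config$proposal_scales, 1L))
  n_acc <- 0L; n_prop <- 0L; keep_i <- 0L

  for (iter in seq_len(config$n_iter)) {
    cond_a <- function(v) lalpha_prior(v) + loglik_state(v, lam, sdllam)
    la <- slice_step(cond_a, la, width = 1)
    ll <- loglik_state(la, lam, sdllam)
    prop <- beta + stats::rnorm(p1, 0, exp(log_sc))
    lam_p <- lam_of(prop)
    sdllam_p <- sum(dl * lam_p)
    ll_p <- loglik_state(la, lam_p, sdllam_p)
    n_prop <- n_prop + 1L
    acc <- is.finite(ll_p) &&
      log(stats::runif(1)) < (ll_p + lbeta_prior(prop)) - (ll + lbeta_prior(beta))
    if (acc) {
      beta <- prop; lam <- lam_p; sdllam <- sdllam_p; ll <- ll_p
      n_acc <- n_acc + 1L
    }
    if (config$adapt && iter <= config$burn_in) {
      log_sc <- adapt_scale(log_sc, acc, config$target_accept, iter)
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- c(exp(la), beta)
      ll_out[keep_i] <- ll
      lp_out[keep_i] <- ll + lalpha_prior(la) + lbeta_prior(beta)
    }
  }
  nm <- c("alpha", paste0("beta", seq_len(p1) - 1L))
  chain <- posterior_chain(draws, nm, lp_out, ll_out,
                           accept_rate = c(beta_block = n_acc / n_prop))

  structure(list(model = "weibull", chain = chain, data = data,
                 prior = prior, link = link, d_s = 1L + p1,
                 loglik_fn = function(par) weibull_loglik(data, par[1L], par[-1L], link),
                 to_unconstrained = function(par) c(log(par[1L]), par[-1L]),
                 from_unconstrained = function(u) c(exp(u[1L]), u[-1L])),
            class = c("weibull_fit", "survbma_fit"))
}

#' @export
print.survbma_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s model fit: %d subjects, %d events, %d parameters, %d posterior draws\n",
              x$model, n_subjects(x$data), event_count(x$data), x$d_s,
              n_draws(x$chain)))
  print(summarize_chain(x$chain))
  invisible(x)
}

#' Posterior predictive survival-time draws
#'
#' Simulates survival times for a subject with covariate vector `x`: each
#' draw picks a stored posterior draw uniformly at random and samples one
#' event time from the corresponding model.  For the cure model a drawn
#' subject may be cured (Poisson count zero); such draws are represented by
#' the study horizon (see [fit_cure()] details).
#'
#' @param fit a `survbma_fit`.
#' @param x covariate vector including the leading intercept 1.
#' @param n_draws_out number of simulated times.
#' @param ... passed to methods.
#' @return numeric vector of length `n_draws_out`.
#' @export
predictive_draws <- function(fit, x, n_draws_out, ...) {
  UseMethod("predictive_draws")
}

#' @rdname predictive_draws
#' @export
predictive_draws.weibull_fit <- function(fit, x, n_draws_out, ...) {
  if (n_draws_out == 0L) return(numeric(0))
  dr <- fit$chain$draws
  idx <- sample.int(nrow(dr), n_draws_out, replace = TRUE)
  a <- dr[idx, 1L]
  beta <- dr[idx, -1L, drop = FALSE]
  eta <- drop(beta %*% x)
  lam <- if (fit$link == "exp") exp(eta) else eta
  u <- stats::runif(n_draws_out)
  (-log(u) * exp(-lam))^(1 / a)
}
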
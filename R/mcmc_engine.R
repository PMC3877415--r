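#' MCMC chain configuration
#'
#' Settings shared by all model fitters: total iterations, burn-in, seed,
#' per-parameter proposal scales and sampler kinds.  Proposal scales are
#' adapted during burn-in only (Robbins-Monro toward a target acceptance
#' rate) and frozen afterwards so the post-burn-in kernel leaves the
#' posterior invariant.  Defaults (20000/5000) are the reduced test-scale
#' run; production-scale runs use `n_iter = 1e5, burn_in = 1e4`.
#'
#' @param n_iter total number of iterations.
#' @param burn_in iterations discarded (and used for adaptation); must be
#'   `< n_iter`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param proposal_scales named or unnamed positive reals, recycled per
#'   parameter; initial random-walk standard deviations.
#' @param sampler_kind `"metropolis"` or `"slice"` per parameter (recycled).
#'   All metropolis-flagged coordinates are updated as one joint
#'   random-walk block; slice-flagged coordinates are updated one at a time
#'   by univariate slice sampling.
#' @param adapt whether to adapt proposal scales during burn-in.
#' @param target_accept target acceptance rate for adaptation (inside the
#'   0.2-0.5 band that keeps random-walk Metropolis efficient).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 20000L, burn_in = 5000L, seed = NULL,
                         proposal_scales = 0.1,
                         sampler_kind = "metropolis",
                         adapt = TRUE, target_accept = 0.3, thin = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter < 1L) stop("`n_iter` must be positive")
  if (burn_in < 0L || burn_in >= n_iter) stop("`burn_in` must satisfy 0 <= burn_in < n_iter")
  if (any(proposal_scales <= 0)) stop("proposal scales must be positive")
  if (!all(sampler_kind %in% c("metropolis", "slice"))) {
    stop("`sampler_kind` entries must be \"metropolis\" or \"slice\"")
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                 proposal_scales = proposal_scales,
                 sampler_kind = sampler_kind, adapt = isTRUE(adapt),
                 target_accept = target_accept, thin = as.integer(thin)),
            class = "chain_config")
}

#' Random-walk Metropolis step
#'
#' One multivariate Gaussian random-walk Metropolis-Hastings update.  The
#' proposal is symmetric, so the acceptance probability is
#' `min(1, exp(log_target(proposal) - log_target(current)))`; rejected
#' proposals return the current state.
#'
#' @param log_target function mapping a real vector to its log target
#'   density (up to a constant); must be finite at `current`.
#' @param current current state (real vector).
#' @param scale positive proposal standard deviation(s), recycled.
#' @param lp_current optional cached `log_target(current)`.
#' @return list with `state`, `log_target` (at the returned state) and
#'   `accepted` (logical).
#' @export
metropolis_step <- function(log_target, current, scale, lp_current = NULL) {
  if (is.null(lp_current)) lp_current <- log_target(current)
  if (!is.finite(lp_current)) stop("log target is not finite at the current state")
  prop <- current + stats::rnorm(length(current), 0, scale)
  lp_prop <- log_target(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_current) {
    list(state = prop, log_target = lp_prop, accepted = TRUE)
  } else {
    list(state = current, log_target = lp_current, accepted = FALSE)
  }
}

#' Univariate slice-sampling step
#'
#' Neal's stepping-out-and-shrinkage slice sampler for a one-dimensional
#' (conditional) log density.  Draws an auxiliary level below the current
#' log density, steps an interval of width `width` out until it brackets
#' the slice (up to `max_steps` expansions each way), then shrinks toward
#' the current point until an in-slice value is found.
#'
#' @param log_target_1d function real -> log density (up to a constant).
#' @param current current value; `log_target_1d(current)` must be finite.
#' @param width initial bracket width.
#' @param max_steps maximum stepping-out expansions per side.
#' @return the new value; its log density is at least the auxiliary level.
#' @export
slice_step <- function(log_target_1d, current, width, max_steps = 50L) {
  lp0 <- log_target_1d(current)
  if (!is.finite(lp0)) stop("log target is not finite at the current state")
  level <- lp0 - stats::rexp(1)
  u <- stats::runif(1)
  lower <- current - width * u
  upper <- lower + width
  steps <- max_steps
  while (steps > 0 && is.finite(lp <- log_target_1d(lower)) && lp > level) {
    lower <- lower - width; steps <- steps - 1L
  }
  steps <- max_steps
  while (steps > 0 && is.finite(lp <- log_target_1d(upper)) && lp > level) {
    upper <- upper + width; steps <- steps - 1L
  }
  repeat {
    prop <- stats::runif(1, lower, upper)
    lp <- log_target_1d(prop)
    if (is.finite(lp) && lp > level) return(prop)
    if (prop < current) lower <- prop else upper <- prop
    if (upper - lower < 1e-300) return(current)
  }
}

## Robbins-Monro update of a log proposal scale toward target acceptance.
adapt_scale <- function(log_scale, accepted, target, iter, rate = 0.66) {
  log_scale + iter^(-rate) * ((if (accepted) 1 else 0) - target)
}

#' Posterior chain container
#'
#' Ordered post-burn-in MCMC draws plus the per-draw log posterior and log
#' likelihood.  Created by [run_chain()] and by the model fitters.
#'
#' @param draws numeric matrix, one row per stored draw.
#' @param parameter_names column names (length = `ncol(draws)`).
#' @param log_posterior per-draw unnormalised log posterior.
#' @param log_likelihood per-draw log likelihood (used for BIC).
#' @param accept_rate optional named acceptance-rate summary.
#' @return an object of class `posterior_chain`.
#' @export
posterior_chain <- function(draws, parameter_names, log_posterior,
                            log_likelihood, accept_rate = NULL) {
  draws <- as.matrix(draws)
  if (length(parameter_names) != ncol(draws)) {
    stop("column count must equal the number of parameter names")
  }
  if (length(log_posterior) != nrow(draws) ||
      length(log_likelihood) != nrow(draws)) {
    stop("log_posterior / log_likelihood must have one entry per draw")
  }
  if (any(!is.finite(log_posterior))) {
    stop("log_posterior must be finite for every stored draw")
  }
  colnames(draws) <- parameter_names
  structure(list(draws = draws, parameter_names = parameter_names,
                 log_posterior = as.numeric(log_posterior),
                 log_likelihood = as.numeric(log_likelihood),
                 accept_rate = accept_rate),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d draws x %d parameters\n",
              nrow(x$draws), ncol(x$draws)))
  print(utils::head(summarize_chain(x)))
  invisible(x)
}

#' Number of stored draws
#' @param chain a [posterior_chain()].
#' @return integer.
#' @export
n_draws <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  nrow(chain$draws)
}

#' Run a generic Metropolis/slice MCMC chain
#'
#' Samples from `exp(log_posterior)` over a real parameter vector.  Each
#' iteration updates the slice-flagged coordinates one at a time by
#' [slice_step()] on their full conditionals and the metropolis-flagged
#' coordinates jointly by one Gaussian random-walk [metropolis_step()].
#' Proposal scales adapt during burn-in only.  With the same seed, config
#' and init the stored chain is bit-identical across runs.
#'
#' @param log_posterior function real-vector -> unnormalised log posterior.
#' @param log_likelihood function real-vector -> log likelihood (stored per
#'   draw, feeds BIC); defaults to `log_posterior`.
#' @param init initial parameter vector with finite `log_posterior`.
#' @param config a [chain_config()].
#' @param parameter_names names for the chain columns.
#' @return a [posterior_chain()] of the post-burn-in draws.
#' @export
run_chain <- function(log_posterior, log_likelihood = NULL, init,
                      config = chain_config(),
                      parameter_names = NULL) {
  stopifnot(inherits(config, "chain_config"))
  if (is.null(log_likelihood)) log_likelihood <- log_posterior
  d <- length(init)
  if (is.null(parameter_names)) {
    parameter_names <- if (!is.null(names(init))) names(init) else
      paste0("par", seq_len(d))
  }
  kind <- rep_len(config$sampler_kind, d)
  scales <- rep_len(config$proposal_scales, d)
  if (!is.null(config$seed)) set.seed(config$seed)

  cur <- as.numeric(init)
  lp <- log_posterior(cur)
  if (!is.finite(lp)) stop("`init` does not have finite log posterior")

  mh_idx <- which(kind == "metropolis")
  sl_idx <- which(kind == "slice")
  log_sc <- log(scales)
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, n_keep, d)
  lp_out <- numeric(n_keep); ll_out <- numeric(n_keep)
  n_acc <- 0L; n_prop <- 0L
  keep_i <- 0L

  for (iter in seq_len(config$n_iter)) {
    for (j in sl_idx) {
      cond <- function(v) { th <- cur; th[j] <- v; log_posterior(th) }
      cur[j] <- slice_step(cond, cur[j], width = exp(log_sc[j]))
    }
    if (length(sl_idx)) lp <- log_posterior(cur)
    if (length(mh_idx)) {
      blk <- function(v) { th <- cur; th[mh_idx] <- v; log_posterior(th) }
      st <- metropolis_step(blk, cur[mh_idx],
                            scale = exp(log_sc[mh_idx]), lp_current = lp)
      cur[mh_idx] <- st$state; lp <- st$log_target
      n_prop <- n_prop + 1L
      if (st$accepted) n_acc <- n_acc + 1L
      if (config$adapt && iter <= config$burn_in) {
        log_sc[mh_idx] <- adapt_scale(log_sc[mh_idx], st$accepted,
                                      config$target_accept, iter)
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- cur
      lp_out[keep_i] <- lp
      ll_out[keep_i] <- log_likelihood(cur)
    }
  }
  posterior_chain(draws, parameter_names, lp_out, ll_out,
                  accept_rate = c(metropolis =
                    if (n_prop) n_acc / n_prop else NA_real_))
}

#' Summarise a posterior chain
#'
#' Per-parameter posterior mean, standard deviation and central 95%
#' credible interval (empirical 2.5% / 97.5% quantiles, default R type-7
#' definition).
#'
#' @param chain a [posterior_chain()] with at least one draw.
#' @param prob credible-interval mass (default 0.95).
#' @return data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
summarize_chain <- function(chain, prob = 0.95) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$draws) == 0L) stop("chain has no stored draws")
  a <- (1 - prob) / 2
  qs <- apply(chain$draws, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  data.frame(parameter = chain$parameter_names,
             mean = colMeans(chain$draws),
             sd = apply(chain$draws, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}

#' Approximate MAP draw
#'
#' The stored draw maximising the unnormalised log posterior; ties broken
#' by the earliest iteration.  Used as the label-switching pivot for the
#' mixture model.
#'
#' @param chain a [posterior_chain()].
#' @return named numeric vector (one row of the draw matrix).
#' @export
map_draw <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$draws) == 0L) stop("chain has no stored draws")
  i <- which.max(chain$log_posterior)  # which.max returns the first maximum
  stats::setNames(chain$draws[i, ], chain$parameter_names)
}

#' Export a chain to a delimited table
#'
#' One row per stored iteration; columns are the parameter names plus
#' `log_posterior` and `log_likelihood`.
#'
#' @param chain a [posterior_chain()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  df <- as.data.frame(chain$draws)
  df$log_posterior <- chain$log_posterior
  df$log_likelihood <- chain$log_likelihood
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
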
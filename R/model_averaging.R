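#' Bayesian information criterion for survival models
#'
#' `BIC = -2 * max_loglik + d_s * log(n_events)`.  In the survival
#' context the effective sample size `n` entering the penalty is the
#' number of uncensored observations (events), not the number of
#' subjects.  A smaller BIC indicates a better fit after accounting for
#' model complexity.
#'
#' @param max_loglik maximised log-likelihood of the model.
#' @param d_s number of free parameters.
#' @param n_events number of events (must be at least 1).
#' @return the BIC value.
#' @export
compute_bic <- function(max_loglik, d_s, n_events) {
  if (n_events < 1) stop("BIC needs at least one event (n_events >= 1)")
  -2 * max_loglik + d_s * log(n_events)
}

#' Maximised log-likelihood from a posterior chain
#'
#' The BIC needs the maximised log-likelihood.  Starting from the stored
#' draw with the highest per-draw log-likelihood, a deterministic
#' Nelder-Mead refinement of `loglik_fn` is run (on an unconstrained
#' transform of the parameters when one is supplied, so positivity and
#' simplex constraints cannot be violated).  The result is never below
#' the best stored draw; if the optimiser fails the best-draw value is
#' returned with a warning.
#'
#' @param chain a [posterior_chain()].
#' @param loglik_fn function mapping a draw (chain row, report scale) to
#'   its log-likelihood.
#' @param to_unconstrained,from_unconstrained optional transform pair
#'   mapping a chain row to an unconstrained vector and back (default
#'   identity).
#' @param maxit Nelder-Mead iteration cap.
#' @return the refined maximised log-likelihood.
#' @export
max_loglik_estimate <- function(chain, loglik_fn,
                                to_unconstrained = identity,
                                from_unconstrained = identity,
                                maxit = 500L) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$draws) == 0L) stop("chain has no stored draws")
  i_best <- which.max(chain$log_likelihood)
  best_draw <- chain$draws[i_best, ]
  best_ll <- chain$log_likelihood[i_best]
  obj <- function(u) {
    v <- tryCatch(loglik_fn(from_unconstrained(u)), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  u0 <- to_unconstrained(best_draw)
  method <- if (length(u0) == 1L) "BFGS" else "Nelder-Mead"
  ctl <- if (method == "BFGS") list(maxit = maxit, reltol = 1e-12)[1] else
    list(maxit = maxit, reltol = 1e-12)
  opt <- tryCatch(
    stats::optim(u0, obj, method = method, control = ctl),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("likelihood maximisation failed; falling back to the best stored draw")
    return(best_ll)
  }
  max(best_ll, -opt$value)
}

#' Per-model fit summary feeding the BIC/BMA workflow
#'
#' @param fit a `survbma_fit` (from [fit_weibull()], [fit_mixture()] or
#'   [fit_cure()]).
#' @param refine refine the maximised log-likelihood with
#'   [max_loglik_estimate()] (default) or use the best stored draw.
#' @return object of class `model_fit_summary`: list with `model_name`,
#'   `max_loglik`, `d_s`, `n_events`, `bic`.
#' @export
model_fit_summary <- function(fit, refine = TRUE) {
  stopifnot(inherits(fit, "survbma_fit"))
  ml <- if (refine) {
    max_loglik_estimate(fit$chain, fit$loglik_fn,
                        fit$to_unconstrained, fit$from_unconstrained)
  } else {
    max(fit$chain$log_likelihood)
  }
  ne <- event_count(fit$data)
  structure(list(model_name = fit$model, max_loglik = ml, d_s = fit$d_s,
                 n_events = ne, bic = compute_bic(ml, fit$d_s, ne)),
            class = "model_fit_summary")
}

#' @export
print.model_fit_summary <- function(x, ...) {
  cat(sprintf("%s: max loglik %.4f, d = %d, events = %d, BIC = %.4f\n",
              x$model_name, x$max_loglik, x$d_s, x$n_events, x$bic))
  invisible(x)
}

#' BIC-approximated Bayesian model averaging weights
#'
#' Posterior model probabilities approximated by
#' `w_s` proportional to `exp(-BIC_s / 2) * p(S = s)`, computed with the
#' minimum-BIC shift so no exponential under/overflows.  The result is
#' invariant to adding a constant to every BIC, and a smaller BIC always
#' yields a larger weight.
#'
#' @param bics finite BIC values, one per candidate model.
#' @param prior_probs prior model probabilities (default uniform `1/S`).
#' @return object of class `bma_result`: list with `weights` (simplex,
#'   named like `bics`), `prior_probs` and `bics`.
#' @examples
#' bma_weights(c(weibull = 687.0953, mixture = 734.0054, cure = 673.1359))
#' @export
bma_weights <- function(bics, prior_probs = NULL) {
  S <- length(bics)
  if (S == 0L) stop("need at least one model")
  if (any(!is.finite(bics))) stop("all BIC values must be finite")
  if (is.null(prior_probs)) prior_probs <- rep(1 / S, S)
  if (length(prior_probs) != S || any(prior_probs < 0) ||
      abs(sum(prior_probs) - 1) > 1e-8) {
    stop("`prior_probs` must be a simplex of the same length as `bics`")
  }
  lw <- -(bics - min(bics)) / 2 + log(prior_probs)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (!is.null(names(bics))) names(w) <- names(bics)
  structure(list(weights = w, prior_probs = prior_probs, bics = bics),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  df <- data.frame(model = if (is.null(names(x$bics)))
    paste0("model", seq_along(x$bics)) else names(x$bics),
    bic = x$bics, weight = x$weights, row.names = NULL)
  print(df)
  invisible(x)
}

#' Bayes factor between two candidate models
#'
#' Ratio of posterior model probabilities corrected for unequal prior
#' probabilities: `(w_1 / w_2) / (p_1 / p_2)`.
#'
#' @param result a [bma_weights()] result.
#' @param s1,s2 model indices or names.
#' @return positive real Bayes factor of `s1` against `s2`.
#' @export
bayes_factor <- function(result, s1, s2) {
  stopifnot(inherits(result, "bma_result"))
  w1 <- result$weights[s1]; w2 <- result$weights[s2]
  p1 <- result$prior_probs[if (is.character(s1)) match(s1, names(result$weights)) else s1]
  p2 <- result$prior_probs[if (is.character(s2)) match(s2, names(result$weights)) else s2]
  if (length(w1) != 1L || length(w2) != 1L || is.na(w1) || is.na(w2)) {
    stop("unknown model index/name")
  }
  if (w2 == 0) stop("denominator model has zero weight")
  unname((w1 / w2) / (p1 / p2))
}

#' Model-averaged posterior predictive draws
#'
#' Each simulated time first selects a model with probability equal to
#' its BMA weight, then draws from that model's posterior predictive for
#' covariate vector `x`; the empirical density converges to the
#' weight-mixed average of the per-model predictive densities.
#'
#' @param fits named list of `survbma_fit` objects.
#' @param weights BMA weights (simplex over `fits`, same order) or a
#'   [bma_weights()] result.
#' @param x covariate vector including the leading intercept 1.
#' @param n_draws_out number of simulated times.
#' @return numeric vector of simulated survival times.
#' @export
bma_predictive <- function(fits, weights, x, n_draws_out) {
  if (inherits(weights, "bma_result")) weights <- weights$weights
  if (length(weights) != length(fits)) {
    stop("one weight per model fit is required")
  }
  if (n_draws_out == 0L) return(numeric(0))
  pick <- sample.int(length(fits), n_draws_out, replace = TRUE,
                     prob = weights)
  out <- numeric(n_draws_out)
  for (s in seq_along(fits)) {
    sel <- pick == s
    if (!any(sel)) next
    if (is.null(fits[[s]])) stop("missing predictive sampler for a positive-weight model")
    out[sel] <- predictive_draws(fits[[s]], x, sum(sel))
  }
  out
}

#' Per-subject posterior prediction intervals
#'
#' For every subject, simulates `n_draws_out` predictive times
#' conditional on that subject's own covariates and returns the central
#' interval bounded by the empirical `(1-level)/2` and `1-(1-level)/2`
#' quantiles.
#'
#' @param fit a `survbma_fit`, or a named list of fits with `weights` for
#'   the model-averaged intervals.
#' @param data a [survival_dataset()] supplying the covariate rows.
#' @param n_draws_out predictive draws per subject.
#' @param level interval mass (default 0.95).
#' @param weights optional BMA weights when `fit` is a list of fits.
#' @return `n x 2` matrix with columns `lower`, `upper`.
#' @export
predictive_intervals <- function(fit, data, n_draws_out = 1000L,
                                 level = 0.95, weights = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  a <- (1 - level) / 2
  n <- n_subjects(data)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("lower", "upper")))
  for (i in seq_len(n)) {
    x <- data$X[i, ]
    dr <- if (inherits(fit, "survbma_fit")) {
      predictive_draws(fit, x, n_draws_out)
    } else {
      bma_predictive(fit, weights, x, n_draws_out)
    }
    out[i, ] <- stats::quantile(dr, c(a, 1 - a), names = FALSE)
  }
  out
}

#' Prediction-interval coverage
#'
#' The percentage of observed times that fall inside their own posterior
#' prediction interval (one interval per subject, bounds inclusive).
#'
#' @param intervals `n x 2` matrix of lower/upper bounds.
#' @param data a [survival_dataset()] with `n` subjects.
#' @return coverage percentage in `[0, 100]`.
#' @export
coverage <- function(intervals, data) {
  stopifnot(inherits(data, "survival_dataset"))
  intervals <- as.matrix(intervals)
  if (nrow(intervals) != n_subjects(data) || ncol(intervals) != 2L) {
    stop("`intervals` must have one (lower, upper) row per subject")
  }
  inside <- data$time >= intervals[, 1L] & data$time <= intervals[, 2L]
  100 * mean(inside)
}
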
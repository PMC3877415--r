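## Independent oracles used across test files.  These deliberately avoid the
## package's own kernels: Weibull quantities go through stats::dweibull /
## pweibull in the (shape, scale) parameterisation, with scale
## b = exp(-lambda/alpha) so that S(t) = exp(-(t/b)^alpha) = exp(-t^alpha
## e^lambda); likelihoods are term-by-term sums; the cure likelihood is a
## truncated enumeration over the latent Poisson counts.

oracle_wb_logpdf <- function(t, alpha, lambda) {
  stats::dweibull(t, shape = alpha, scale = exp(-lambda / alpha), log = TRUE)
}

oracle_wb_logsurv <- function(t, alpha, lambda) {
  stats::pweibull(t, shape = alpha, scale = exp(-lambda / alpha),
                  lower.tail = FALSE, log.p = TRUE)
}

oracle_weibull_loglik <- function(data, alpha, beta, link = "identity") {
  total <- 0
  for (i in seq_along(data$time)) {
    eta <- sum(data$X[i, ] * beta)
    lam <- if (link == "exp") exp(eta) else eta
    total <- total + if (data$status[i] == 1) {
      oracle_wb_logpdf(data$time[i], alpha, lam)
    } else {
      oracle_wb_logsurv(data$time[i], alpha, lam)
    }
  }
  total
}

oracle_mixture_loglik <- function(data, weights, shapes, coefs) {
  total <- 0
  K <- length(weights)
  for (i in seq_along(data$time)) {
    dens <- 0; surv <- 0
    for (m in seq_len(K)) {
      lam <- sum(data$X[i, ] * coefs[m, ])
      dens <- dens + weights[m] * exp(oracle_wb_logpdf(data$time[i], shapes[m], lam))
      surv <- surv + weights[m] * exp(oracle_wb_logsurv(data$time[i], shapes[m], lam))
    }
    total <- total + if (data$status[i] == 1) log(dens) else log(surv)
  }
  total
}

## complete-data cure likelihood summed over N_i = delta_i .. n_max:
## L_i = sum_N  Pois(N | theta_i) * [N f(t_i)]^delta * S(t_i)^(N - delta)
oracle_cure_loglik_enum <- function(data, alpha, lambda, beta,
                                    n_max = 200L) {
  total <- 0
  for (i in seq_along(data$time)) {
    theta <- exp(sum(data$X[i, ] * beta))
    f <- exp(oracle_wb_logpdf(data$time[i], alpha, lambda))
    S <- exp(oracle_wb_logsurv(data$time[i], alpha, lambda))
    d <- data$status[i]
    Ns <- seq.int(d, n_max)
    terms <- stats::dpois(Ns, theta) * (Ns * f)^d * S^(Ns - d)
    total <- total + log(sum(terms))
  }
  total
}

## small mixed-censoring fixture shared by the likelihood-oracle tests
fixture_mixed5 <- function() {
  survival_dataset(
    time = c(0.4, 1.3, 2.2, 3.1, 5.0),
    status = c(1, 0, 1, 1, 0),
    covariates = cbind(x1 = c(-1.2, 0.3, 0.8, -0.5, 1.6),
                       x2 = c(0.7, -0.9, 0.1, 1.1, -0.4)))
}

expect_simplex <- function(w, tol = 1e-12) {
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = tol)
}
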
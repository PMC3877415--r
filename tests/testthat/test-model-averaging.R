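test_that("compute_bic follows the events-based formula", {
  expect_equal(compute_bic(0, 0, 1), 0)
  expect_equal(compute_bic(-340.3, 7, 138), 680.6 + 7 * log(138))
  ## one extra parameter at equal fit costs log(n)
  expect_equal(compute_bic(-10, 3, 50) - compute_bic(-10, 2, 50), log(50))
  expect_error(compute_bic(-10, 2, 0), "at least one")
})

test_that("bma_weights is a shift-invariant softmax of -BIC/2", {
  ## all equal: uniform
  r <- bma_weights(rep(100, 4))
  expect_equal(unname(r$weights), rep(0.25, 4))
  expect_simplex(r$weights)

  ## shift invariance
  b <- c(687.0953, 734.0054, 673.1359)
  expect_equal(bma_weights(b)$weights, bma_weights(b + 1234.5)$weights,
               tolerance = 1e-12)
  ## monotone: smaller BIC, larger weight
  w <- bma_weights(c(10, 12, 14))$weights
  expect_true(all(diff(w) < 0))
  ## closed form against manual computation
  expect_equal(unname(bma_weights(c(10, 12))$weights),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  ## non-uniform priors
  r2 <- bma_weights(c(10, 10), prior_probs = c(0.8, 0.2))
  expect_equal(unname(r2$weights), c(0.8, 0.2))
  expect_error(bma_weights(numeric(0)), "at least one")
  expect_error(bma_weights(c(1, Inf)), "finite")
  expect_error(bma_weights(c(1, 2), prior_probs = c(0.5, 0.6)), "simplex")
})

test_that("bayes_factor is the prior-adjusted posterior odds", {
  r <- bma_weights(c(weibull = 10, cure = 10))
  expect_equal(bayes_factor(r, "weibull", "cure"), 1)
  expect_equal(bayes_factor(r, 1, 1), 1)
  r2 <- bma_weights(c(a = 10, b = 12))
  expect_equal(bayes_factor(r2, "a", "b"), exp(1), tolerance = 1e-12)
  ## prior adjustment cancels the prior's effect on the weights
  r3 <- bma_weights(c(a = 10, b = 12), prior_probs = c(0.9, 0.1))
  expect_equal(bayes_factor(r3, "a", "b"), exp(1), tolerance = 1e-12)
  expect_error(bayes_factor(r2, "a", "zz"), "unknown")
})

test_that("max_loglik_estimate refines the best stored draw", {
  d <- simulate_weibull_data(n = 100, beta = c(-0.3, 0.2), shape = 1.2,
                             target_censoring = 0.2, seed = 101)
  f <- fit_weibull(d, config = chain_config(2000, 500, seed = 111))
  ml <- max_loglik_estimate(f$chain, f$loglik_fn, f$to_unconstrained,
                            f$from_unconstrained)
  ## never below the best stored draw
  expect_gte(ml, max(f$chain$log_likelihood))

  ## a chain already containing the exact optimum returns its likelihood
  best <- optim(c(0, -0.3, 0.2),
                function(u) -f$loglik_fn(c(exp(u[1]), u[-1])),
                control = list(reltol = 1e-14, maxit = 2000))
  par_best <- c(exp(best$par[1]), best$par[-1])
  ch <- posterior_chain(matrix(par_best, 1, 3, byrow = TRUE),
                        c("alpha", "beta0", "beta1"), 0, -best$value)
  expect_equal(max_loglik_estimate(ch, f$loglik_fn, f$to_unconstrained,
                                   f$from_unconstrained),
               -best$value, tolerance = 1e-6)
})

test_that("exponential closed-form maximum is recovered with alpha fixed at 1", {
  set.seed(5)
  tt <- rexp(60, 0.7)
  d <- survival_dataset(tt, rep(1, 60))
  ## likelihood as a function of beta0 only (alpha frozen at 1)
  ll <- function(par) weibull_loglik(d, 1, par)
  lam_hat <- log(60 / sum(tt))
  closed <- 60 * lam_hat - 60
  ch <- posterior_chain(matrix(lam_hat + 0.3, 1, 1), "beta0", 0,
                        ll(lam_hat + 0.3))
  expect_equal(max_loglik_estimate(ch, ll), closed, tolerance = 1e-6)
})

test_that("model_fit_summary assembles the BIC inputs", {
  d <- simulate_weibull_data(n = 80, beta = c(-0.3, 0.2), shape = 1.2,
                             target_censoring = 0.2, seed = 121)
  f <- fit_weibull(d, config = chain_config(1500, 500, seed = 131))
  sm <- model_fit_summary(f)
  expect_identical(sm$model_name, "weibull")
  expect_identical(sm$d_s, 3L)
  expect_identical(sm$n_events, event_count(d))
  expect_equal(sm$bic, compute_bic(sm$max_loglik, sm$d_s, sm$n_events))
})

test_that("bma_predictive mixes per-model samplers by weight", {
  d <- survival_dataset(c(1, 2), c(1, 1))
  f <- fit_weibull(d, config = chain_config(300, 100, seed = 2))
  ## two degenerate 'models': point predictives at 1 and at 2
  f1 <- f; f2 <- f
  f1$chain <- posterior_chain(matrix(c(200, 0), 10, 2, byrow = TRUE),
                              c("alpha", "beta0"), rep(0, 10), rep(0, 10))
  f2$chain <- posterior_chain(matrix(c(200, -200 * log(2)), 10, 2,
                                     byrow = TRUE),
                              c("alpha", "beta0"), rep(0, 10), rep(0, 10))
  ## alpha huge makes draws concentrate at exp(-lambda/alpha): 1 and 2
  set.seed(3)
  dr <- bma_predictive(list(f1, f2), c(0.25, 0.75), x = 1,
                       n_draws_out = 8000)
  expect_equal(mean(dr), 0.25 * 1 + 0.75 * 2, tolerance = 0.02)
  expect_length(bma_predictive(list(f1, f2), c(0.5, 0.5), 1, 0), 0)
  ## weight 1 on one model reproduces that model's predictive
  dr1 <- bma_predictive(list(f1, f2), c(1, 0), x = 1, n_draws_out = 100)
  expect_equal(mean(dr1), 1, tolerance = 0.01)
  expect_error(bma_predictive(list(f1), c(0.5, 0.5), 1, 10), "one weight")
})

test_that("coverage counts subjects inside their own intervals", {
  d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 0, 1))
  all_in <- cbind(rep(0, 4), rep(Inf, 4))
  expect_equal(coverage(all_in, d), 100)
  none <- cbind(rep(100, 4), rep(101, 4))
  expect_equal(coverage(none, d), 0)
  half <- cbind(c(0, 0, 100, 100), c(10, 10, 101, 101))
  expect_equal(coverage(half, d), 50)
  expect_error(coverage(all_in[1:2, ], d), "per subject")
})
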
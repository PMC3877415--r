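make_params <- function(w = c(0.3, 0.7), a = c(4, 0.8),
                        B = rbind(c(1.2, -0.3, 0.3), c(-1.7, 0.2, -0.3))) {
  mixture_params(w, a, B)
}

test_that("mixture_logdensity reduces correctly and matches direct summation", {
  law <- weibull_law(1.7, -0.4)
  p1 <- mixture_params(1, 1.7, matrix(-0.4, 1, 1))
  tt <- c(0.3, 1, 2.5)
  expect_equal(mixture_logdensity(tt, 1, p1), weibull_logpdf(tt, law),
               tolerance = 1e-14)

  ## identical components collapse to one
  pid <- mixture_params(c(0.5, 0.5), c(1.7, 1.7),
                        rbind(c(-0.4, 0.2), c(-0.4, 0.2)))
  expect_equal(mixture_logdensity(1.3, c(1, 0.5), pid),
               weibull_logpdf(1.3, weibull_law(1.7, -0.4 + 0.1)),
               tolerance = 1e-14)

  ## direct two-term sum oracle at t = 1
  p <- make_params()
  x <- c(1, 0.4, -0.2)
  direct <- log(0.3 * exp(oracle_wb_logpdf(1, 4, sum(x * p$coefs[1, ]))) +
                0.7 * exp(oracle_wb_logpdf(1, 0.8, sum(x * p$coefs[2, ]))))
  expect_equal(mixture_logdensity(1, x, p), direct, tolerance = 1e-12)

  ## log-sum-exp stability: extreme lambda must not overflow to NaN
  pext <- mixture_params(c(0.5, 0.5), c(1, 1),
                         rbind(c(600, 0, 0), c(-600, 0, 0)))
  expect_true(is.finite(mixture_logdensity(1, c(1, 0, 0), pext)))
  expect_error(mixture_params(c(0.5, 0.6), c(1, 1), diag(2)), "simplex")
})

test_that("mixture observed log-likelihood matches the brute-force oracle", {
  d <- fixture_mixed5()
  p <- make_params()
  expect_equal(mixture_loglik(d, p),
               oracle_mixture_loglik(d, p$weights, p$shapes, p$coefs),
               tolerance = 1e-10)

  ## equal components reduce to the single-Weibull likelihood
  peq <- mixture_params(c(0.4, 0.6), c(1.3, 1.3),
                        rbind(c(-0.5, 0.2, -0.1), c(-0.5, 0.2, -0.1)))
  expect_equal(mixture_loglik(d, peq), weibull_loglik(d, 1.3, c(-0.5, 0.2, -0.1)),
               tolerance = 1e-12)

  ## permutation invariance (exact)
  pswap <- mixture_params(p$weights[2:1], p$shapes[2:1], p$coefs[2:1, ])
  expect_identical(mixture_loglik(d, p), mixture_loglik(d, pswap))

  ## one weight -> 1 converges to the single-Weibull likelihood (components
  ## kept mildly separated so the 1e-9 leakage term is truly negligible)
  eps <- 1e-9
  Bn <- rbind(c(-0.2, 0.1, -0.1), c(-0.6, 0.2, 0.1))
  plim <- mixture_params(c(1 - eps, eps), c(1.2, 0.9), Bn)
  expect_equal(mixture_loglik(d, plim),
               weibull_loglik(d, 1.2, Bn[1, ]), tolerance = 1e-6)
})

test_that("allocation probabilities follow the membership conditional", {
  d <- fixture_mixed5()
  ## degenerate weight: everyone in component 1
  pdeg <- mixture_params(c(1, 0), c(4, 0.8),
                         rbind(c(1.2, -0.3, 0.3), c(-1.7, 0.2, -0.3)))
  set.seed(1)
  expect_true(all(allocation_step(d, pdeg) == 1L))

  ## identical components: uniform membership
  peq <- mixture_params(c(0.5, 0.5), c(1.3, 1.3),
                        rbind(c(-0.5, 0.2, -0.1), c(-0.5, 0.2, -0.1)))
  P <- allocation_probs(d, peq)
  expect_equal(P, matrix(0.5, 5, 2), ignore_attr = TRUE)

  ## well-separated components: a time drawn deep inside component 1's
  ## support is assigned there with near certainty
  dsep <- survival_dataset(0.9, 1, covariates = matrix(0, 1, 2,
                           dimnames = list(NULL, c("x1", "x2"))))
  psep <- mixture_params(c(0.5, 0.5), c(8, 8),
                         rbind(c(0, 0, 0), c(-20, 0, 0)))
  P <- allocation_probs(dsep, psep)
  direct <- exp(oracle_wb_logpdf(0.9, 8, 0)) /
    (exp(oracle_wb_logpdf(0.9, 8, 0)) + exp(oracle_wb_logpdf(0.9, 8, -20)))
  expect_equal(P[1, 1], direct, tolerance = 1e-10)
  expect_gt(P[1, 1], 0.99)
})

test_that("weight_update is the conjugate Dirichlet draw", {
  ## empty counts with phi = 1: mean (0.5, 0.5)
  set.seed(2)
  draws <- t(replicate(4000, weight_update(integer(0), K = 2, phi = 1)))
  expect_equal(colMeans(draws), c(0.5, 0.5), tolerance = 0.02)
  for (i in 1:10) expect_simplex(weight_update(integer(0), 2, 1), tol = 1e-9)

  ## counts (98, 2), phi = 1: mean (99, 3)/102
  z <- rep(c(1L, 2L), c(98, 2))
  draws <- t(replicate(4000, weight_update(z, K = 2, phi = 1)))
  expect_equal(colMeans(draws), c(99, 3) / 102, tolerance = 0.02)

  ## single component: weight identically 1
  expect_equal(weight_update(rep(1L, 5), K = 1, phi = 1), 1)
})

test_that("reorder_chain restores a constructed label-switched chain", {
  ## build a chain whose draws concentrate around two well-separated
  ## component parameter sets, with labels swapped on a random half
  set.seed(33)
  n <- 400
  truth1 <- c(w = 0.3, alpha = 4.0, beta0 = 1.2)
  truth2 <- c(w = 0.7, alpha = 0.8, beta0 = -1.7)
  noise <- function(s) rnorm(n, 0, s)
  draws <- cbind(truth1["w"] + noise(0.02), truth2["w"] - noise(0.02),
                 truth1["alpha"] + noise(0.1), truth2["alpha"] + noise(0.05),
                 truth1["beta0"] + noise(0.1), truth2["beta0"] + noise(0.1))
  draws[, 2] <- 1 - draws[, 1]
  swapped <- sample(c(TRUE, FALSE), n, replace = TRUE)
  draws[swapped, ] <- draws[swapped, c(2, 1, 4, 3, 6, 5)]
  nm <- c("w.1", "w.2", "alpha.1", "alpha.2", "beta0.1", "beta0.2")
  lp <- rnorm(n); lp[1] <- 10  # make an unswapped draw the MAP pivot
  swapped[1] <- FALSE
  draws[1, ] <- c(truth1["w"], truth2["w"], truth1["alpha"], truth2["alpha"],
                  truth1["beta0"], truth2["beta0"])
  ch <- posterior_chain(draws, nm, lp, lp)

  ## raw chain is bimodal in alpha.1; reordered one is unimodal at truth
  re <- reorder_chain(ch, K = 2)
  expect_equal(mean(re$draws[, "alpha.1"]), 4.0, tolerance = 0.05)
  expect_equal(mean(re$draws[, "beta0.1"]), 1.2, tolerance = 0.05)
  expect_equal(mean(re$draws[, "w.1"]), 0.3, tolerance = 0.02)
  ## per-draw log posterior / likelihood untouched
  expect_identical(re$log_posterior, ch$log_posterior)
  expect_identical(re$log_likelihood, ch$log_likelihood)

  ## already-aligned chain unchanged; K = 1 is the identity
  re2 <- reorder_chain(re, K = 2)
  expect_identical(re2$draws, re$draws)
  expect_identical(reorder_chain(ch, K = 1), ch)
  bad <- posterior_chain(draws[, 1:5], nm[1:5], lp, lp)
  expect_error(reorder_chain(bad, K = 2), "block structure")
})

test_that("fit_mixture recovers a well-separated mixture and is reproducible", {
  d <- simulate_mixture_data(n = 250, weights = c(0.35, 0.65),
                             shapes = c(4, 0.8),
                             coefs = rbind(c(1.2, -0.3), c(-1.5, 0.3)),
                             target_censoring = 0.2, seed = 41)
  cfg <- chain_config(n_iter = 4000, burn_in = 1500, seed = 51)
  f <- fit_mixture(d, K = 2, config = cfg)
  sm <- summarize_chain(f$chain_reordered)
  tv <- c(0.35, 0.65, 4, 0.8, 1.2, -0.3, -1.5, 0.3)
  expect_true(all(abs(sm$mean - tv) / sm$sd < 3.5))

  f2 <- fit_mixture(d, K = 2, config = cfg)
  expect_identical(f$chain$draws, f2$chain$draws)

  ## stored log-likelihood is the observed-data (marginal) likelihood
  j <- 100
  par <- f$chain$draws[j, ]
  pj <- mixture_params(par[1:2], par[3:4],
                       rbind(par[5:6], par[7:8]))
  expect_equal(f$chain$log_likelihood[j], mixture_loglik(d, pj),
               tolerance = 1e-8)
  expect_equal(f$d_s, 2L + 2L * 2L + 1L)
  expect_error(fit_mixture(survival_dataset(1, 1), K = 2), "at least K")
})

test_that("K = 1 mixture agrees with the single Weibull model in distribution", {
  d <- simulate_weibull_data(n = 120, beta = c(-0.4, 0.3), shape = 1.3,
                             target_censoring = 0.25, seed = 61)
  fm <- fit_mixture(d, K = 1, config = chain_config(3000, 1000, seed = 71))
  fw <- fit_weibull(d, config = chain_config(3000, 1000, seed = 72))
  sm <- summarize_chain(fm$chain)
  sw <- summarize_chain(fw$chain)
  ## posterior means of (alpha, beta) agree within Monte-Carlo error
  expect_equal(sm$mean[sm$parameter == "alpha.1"],
               sw$mean[sw$parameter == "alpha"], tolerance = 0.05)
  expect_equal(sm$mean[sm$parameter == "beta0.1"],
               sw$mean[sw$parameter == "beta0"], tolerance = 0.05)
  expect_true(all(fm$chain$draws[, "w.1"] == 1))
})
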
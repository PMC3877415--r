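test_that("theta link and cure fraction follow their closed forms", {
  expect_equal(theta_link(c(1, 0, 0), c(0, 1, 2)), 1)
  expect_equal(theta_link(c(1, 0, 0), c(0.1611, 1, 2)), exp(0.1611))
  expect_equal(theta_link(c(1, 1), c(1, -1)), 1)
  expect_error(theta_link(c(1, 1), c(1, 2, 3)), "mismatch")

  expect_equal(cure_fraction(0), 1)
  expect_equal(cure_fraction(log(2)), 0.5)
  expect_equal(cure_fraction(1e8), 0, tolerance = 1e-12)
  th <- seq(0, 5, by = 0.5)
  expect_true(all(diff(cure_fraction(th)) < 0))
  expect_error(cure_fraction(-1), "non-negative")
})

test_that("pop_logsurv interpolates between 1 and the cure fraction", {
  p <- cure_params(alpha = 1, lambda = 0, beta = log(2))
  expect_equal(pop_logsurv(0, 1, p), 0)
  ## t = 1, theta = 2: -2 (1 - e^-1)
  p2 <- cure_params(1, 0, log(2))
  expect_equal(pop_logsurv(1, 1, p2), -2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(pop_logsurv(1, 1, p2), -1.26424, tolerance = 1e-5)
  ## plateau at -theta for large t
  p3 <- cure_params(1.3, 0.2, log(1.2))
  expect_equal(pop_logsurv(500, 1, p3), -1.2, tolerance = 1e-8)
  ## non-increasing on a grid
  g <- pop_logsurv(seq(0, 20, by = 0.25), 1, p3)
  expect_true(all(diff(g) <= 0))
})

test_that("population hazard equals theta times the latent density", {
  ## -d/dt log S_pop = theta f(t), checked by central differences
  p <- cure_params(alpha = 1.6, lambda = -0.5, beta = c(0.3, 0.2))
  x <- c(1, -0.7)
  theta <- theta_link(x, p$beta)
  law <- weibull_law(p$alpha, p$lambda)
  h <- 1e-5
  for (t in c(0.3, 1, 2.7, 6)) {
    num <- -(pop_logsurv(t + h, x, p) - pop_logsurv(t - h, x, p)) / (2 * h)
    expect_equal(num, theta * exp(weibull_logpdf(t, law)), tolerance = 1e-6)
  }
})

test_that("observed cure likelihood matches the latent-count enumeration oracle", {
  d <- survival_dataset(time = c(0.5, 1.2, 2.4, 4.1),
                        status = c(1, 0, 1, 0),
                        covariates = cbind(x1 = c(-0.8, 0.2, 1.1, -0.3)))
  for (par in list(c(1, 0, 0.2, -0.4), c(0.8, -0.6, 0.5, 0.3),
                   c(1.5, -1, 0, 0))) {
    p <- cure_params(par[1], par[2], par[3:4])
    expect_equal(cure_loglik(d, p),
                 oracle_cure_loglik_enum(d, par[1], par[2], par[3:4]),
                 tolerance = 1e-10)
  }
  ## all censored: -sum theta_i F(t_i)
  dc <- survival_dataset(c(1, 3), c(0, 0))
  p <- cure_params(1, 0, 0.4)
  expect_equal(cure_loglik(dc, p),
               -exp(0.4) * sum(1 - exp(-c(1, 3))), tolerance = 1e-12)
})

test_that("latent_count_step samples the documented conditional", {
  d1 <- survival_dataset(1, 0, covariates = matrix(0, 1, 1,
                         dimnames = list(NULL, "x1")))
  ## theta -> 0: always N = delta
  p0 <- cure_params(1, 0, c(-30, 0))
  set.seed(1)
  expect_true(all(replicate(50, latent_count_step(d1, p0)) == 0L))

  ## censored subject with theta S(t) = 0.5: mean of N ~ 0.5
  ## S(1) = e^-1 under alpha=1, lambda=0, so choose theta = 0.5 e
  p <- cure_params(1, 0, c(log(0.5 * exp(1)), 0))
  set.seed(2)
  Ns <- replicate(10000, latent_count_step(d1, p))
  expect_equal(mean(Ns), 0.5, tolerance = 0.05)

  ## conditional law matches enumeration of P(N | data) for one subject:
  ## P(N = delta + k) = Pois(k | theta S)
  dev <- survival_dataset(1, 1, covariates = matrix(0, 1, 1,
                          dimnames = list(NULL, "x1")))
  set.seed(3)
  Ns <- replicate(20000, latent_count_step(dev, p))
  expect_true(all(Ns >= 1L))
  lamS <- exp(log(0.5 * exp(1))) * exp(-1)
  for (k in 0:3) {
    expect_equal(mean(Ns == 1L + k), dpois(k, lamS), tolerance = 0.02)
  }
})

test_that("collapsed and augmented samplers agree on a small dataset", {
  d <- simulate_cure_data(n = 120, beta = c(0.3, -0.4), shape = 1.1,
                          lambda = -0.5, target_censoring = 0.4, seed = 81)
  cfgc <- chain_config(6000, 2000, seed = 91)
  cfga <- chain_config(12000, 4000, seed = 92)
  fc <- fit_cure(d, config = cfgc, sampler = "collapsed")
  fa <- fit_cure(d, config = cfga, sampler = "augmented")
  sc <- summarize_chain(fc$chain)
  sa <- summarize_chain(fa$chain)
  ## posterior means agree within combined Monte-Carlo error
  tolv <- 3 * sqrt(sc$sd^2 / 200 + sa$sd^2 / 100) + 0.06 * sc$sd
  expect_true(all(abs(sc$mean - sa$mean) < pmax(tolv, 0.08)))

  ## both samplers store the observed-data likelihood
  j <- 10
  par <- fc$chain$draws[j, ]
  expect_equal(fc$chain$log_likelihood[j],
               cure_loglik(d, cure_params(par[1], par[2], par[-(1:2)])),
               tolerance = 1e-8)
  par <- fa$chain$draws[j, ]
  expect_equal(fa$chain$log_likelihood[j],
               cure_loglik(d, cure_params(par[1], par[2], par[-(1:2)])),
               tolerance = 1e-8)

  ## reproducibility
  fc2 <- fit_cure(d, config = cfgc, sampler = "collapsed")
  expect_identical(fc$chain$draws, fc2$chain$draws)
  expect_equal(fc$d_s, 2L + 2L)
})

test_that("population_cure_summary averages per-subject cure probabilities", {
  d <- survival_dataset(c(1, 2), c(1, 1),
                        covariates = cbind(x1 = c(0.5, -0.5)))
  f <- fit_cure(d, config = chain_config(400, 100, seed = 3))
  ## constant chain at beta = 0: theta = 1 everywhere, cure prob exp(-1)
  f$chain <- posterior_chain(matrix(c(1, 0, 0, 0), 50, 4, byrow = TRUE),
                             c("alpha", "lambda", "beta0", "beta1"),
                             rep(0, 50), rep(0, 50))
  expect_equal(population_cure_summary(f), rep(exp(-1), 50))
  ## single subject with theta = log 2: cure probability one half
  f$chain <- posterior_chain(matrix(c(1, 0, log(log(2)), 0), 50, 4,
                                    byrow = TRUE),
                             c("alpha", "lambda", "beta0", "beta1"),
                             rep(0, 50), rep(0, 50))
  X1 <- matrix(c(1, 0), 1, 2)
  expect_equal(unique(population_cure_summary(f, X1)), 0.5)
})
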
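#' Mixture-model parameter set
#'
#' A `K`-component Weibull mixture: weights `w` on the simplex, one shape
#' `alpha_m` per component and one coefficient vector `beta_m` per
#' component acting on the component log-scale, `lambda_im = x_i' beta_m`.
#'
#' @param weights length-`K` nonnegative weights summing to one.
#' @param shapes length-`K` positive shapes.
#' @param coefs `K x (p+1)` coefficient matrix (one row per component,
#'   intercept first).
#' @return object of class `mixture_params`.
#' @export
mixture_params <- function(weights, shapes, coefs) {
  coefs <- as.matrix(coefs)
  K <- length(weights)
  if (length(shapes) != K || nrow(coefs) != K) {
    stop("`weights`, `shapes` and `coefs` rows must all have length K")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be a simplex (nonnegative, summing to 1)")
  }
  if (any(shapes <= 0)) stop("shapes must be positive")
  structure(list(K = K, weights = weights, shapes = shapes, coefs = coefs),
            class = "mixture_params")
}

#' Prior specification for the Weibull mixture model
#'
#' Symmetric `Dirichlet(phi, ..., phi)` prior on the weights (default
#' `phi = 1`), independent `Gamma(u_alpha, v_alpha)` priors on each shape,
#' and independent `N(0, sigma2_beta)` priors on every coefficient
#' (diagonal prior covariance).  `u_gamma`/`v_gamma` are the Gamma
#' hyperparameters of the covariate-free variant, where the component
#' scale `gamma_m = exp(beta0_m)` gets a Gamma prior instead of the normal
#' prior on `beta0_m`; they are honoured only for intercept-only designs
#' with `gamma_prior = TRUE`.
#'
#' @param phi positive symmetric Dirichlet hyperparameter.
#' @param u_alpha,v_alpha positive Gamma shape/rate for each `alpha_m`.
#' @param sigma2_beta positive prior variance of each coefficient.
#' @param u_gamma,v_gamma positive Gamma shape/rate for the scale in the
#'   covariate-free variant.
#' @param gamma_prior use the Gamma-scale prior for intercept-only designs.
#' @return object of class `mixture_prior`.
#' @export
mixture_prior <- function(phi = 1, u_alpha = 0.01, v_alpha = 0.01,
                          sigma2_beta = 100, u_gamma = 0.01,
                          v_gamma = 0.01, gamma_prior = FALSE) {
  vals <- c(phi, u_alpha, v_alpha, sigma2_beta, u_gamma, v_gamma)
  if (any(vals <= 0)) stop("all prior hyperparameters must be positive")
  structure(list(phi = phi, u_alpha = u_alpha, v_alpha = v_alpha,
                 sigma2_beta = sigma2_beta, u_gamma = u_gamma,
                 v_gamma = v_gamma, gamma_prior = isTRUE(gamma_prior)),
            class = "mixture_prior")
}

## n x K matrices of per-component log density / log survival at the data
mix_component_logf <- function(tm, lt, X, params) {
  K <- params$K
  out_f <- matrix(NA_real_, length(tm), K)
  out_S <- matrix(NA_real_, length(tm), K)
  for (m in seq_len(K)) {
    a <- params$shapes[m]
    lam <- drop(X %*% params$coefs[m, ])
    H <- exp(a * lt + lam)               # cumulative hazard t^a e^lam
    out_f[, m] <- log(a) + (a - 1) * lt + lam - H
    out_S[, m] <- -H
  }
  list(logf = out_f, logS = out_S)
}

## row-wise log-sum-exp without apply(): pmax/exp column sweeps only
log_sum_exp_rows <- function(M) {
  K <- ncol(M)
  mx <- M[, 1L]
  if (K > 1L) for (m in 2:K) mx <- pmax.int(mx, M[, m])
  s <- exp(M[, 1L] - mx)
  if (K > 1L) for (m in 2:K) s <- s + exp(M[, m] - mx)
  mx + log(s)
}

add_per_column <- function(M, v) {
  for (m in seq_along(v)) M[, m] <- M[, m] + v[m]
  M
}

#' Mixture log-density
#'
#' `log sum_m w_m f(t | alpha_m, lambda_m = x' beta_m)`, evaluated with a
#' log-sum-exp so extreme log-scales cannot overflow.
#'
#' @param t positive time(s).
#' @param x covariate vector (intercept first) or matrix with one row per
#'   element of `t`.
#' @param params a [mixture_params()].
#' @return log mixture density, vectorised over `t`.
#' @export
mixture_logdensity <- function(t, x, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(t <= 0)) stop("`t` must be positive")
  X <- if (is.matrix(x)) x else matrix(x, nrow = length(t),
                                       ncol = length(x), byrow = TRUE)
  cmp <- mix_component_logf(t, log(t), X, params)
  lw <- log(params$weights)
  log_sum_exp_rows(add_per_column(cmp$logf, lw))
}

#' Mixture log-survival
#'
#' `log sum_m w_m S(t | alpha_m, lambda_m = x' beta_m)`.
#'
#' @inheritParams mixture_logdensity
#' @return log mixture survival probability, vectorised over `t`.
#' @export
mixture_logsurv <- function(t, x, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  X <- if (is.matrix(x)) x else matrix(x, nrow = length(t),
                                       ncol = length(x), byrow = TRUE)
  cmp <- mix_component_logf(pmax(t, .Machine$double.xmin), log(pmax(t, .Machine$double.xmin)), X, params)
  logS <- cmp$logS
  logS[t == 0, ] <- 0
  lw <- log(params$weights)
  log_sum_exp_rows(sweep(logS, 2, lw, `+`))
}

#' Observed-data mixture log-likelihood
#'
#' Marginal over the latent allocations: events contribute the log mixture
#' density, censored subjects the log mixture survivor function.
#'
#' @param data a [survival_dataset()].
#' @param params a [mixture_params()].
#' @return log-likelihood value.
#' @export
mixture_loglik <- function(data, params) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(params, "mixture_params"))
  cmp <- mix_component_logf(data$time, log(data$time), data$X, params)
  lw <- log(params$weights)
  ld <- log_sum_exp_rows(add_per_column(cmp$logf, lw))
  ls <- log_sum_exp_rows(add_per_column(cmp$logS, lw))
  sum(data$status * ld + (1 - data$status) * ls)
}

#' Latent-allocation Gibbs step
#'
#' Samples component memberships from their full conditional:
#' `P(Z_i = m)` proportional to `w_m f_m(t_i)^delta_i S_m(t_i)^(1-delta_i)`
#' (censored subjects contribute through the survivor function).
#'
#' @param data a [survival_dataset()].
#' @param params a [mixture_params()].
#' @return integer vector of component indices in `1..K`.
#' @export
allocation_step <- function(data, params) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(params, "mixture_params"))
  P <- allocation_probs(data, params)
  sample_categorical_rows(P)
}

#' Posterior membership probabilities
#'
#' The normalised allocation probabilities used by [allocation_step()].
#'
#' @inheritParams allocation_step
#' @return `n x K` matrix of probabilities, rows summing to one.
#' @export
allocation_probs <- function(data, params) {
  cmp <- mix_component_logf(data$time, log(data$time), data$X, params)
  L <- data$status * cmp$logf + (1 - data$status) * cmp$logS
  L <- add_per_column(L, log(params$weights))
  L[, params$weights == 0] <- -Inf
  K <- ncol(L)
  mx <- L[, 1L]
  if (K > 1L) for (m in 2:K) mx <- pmax.int(mx, L[, m])
  if (any(!is.finite(mx))) {
    stop("numerical degeneracy: a subject has zero membership mass in every component")
  }
  P <- exp(L - mx)
  P / rowSums(P)
}

## draw one categorical index per row of a probability matrix
sample_categorical_rows <- function(P) {
  n <- nrow(P); K <- ncol(P)
  if (K == 1L) return(rep.int(1L, n))
  u <- stats::runif(n)
  cum <- P
  for (m in 2:K) cum[, m] <- cum[, m - 1L] + P[, m]
  z <- rowSums(u > cum) + 1L
  as.integer(pmin(z, K))
}

#' Conjugate Dirichlet weight update
#'
#' Draws mixture weights from `Dirichlet(phi + n_1, ..., phi + n_K)` where
#' `n_m` counts the subjects currently allocated to component `m`.
#'
#' @param z integer allocation vector (values in `1..K`).
#' @param K number of components.
#' @param phi positive symmetric Dirichlet hyperparameter.
#' @return a length-`K` simplex draw.
#' @export
weight_update <- function(z, K, phi = 1) {
  counts <- tabulate(z, nbins = K)
  g <- stats::rgamma(K, shape = phi + counts, rate = 1)
  g / sum(g)
}

## all permutations of 1..K (K small)
all_perms <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in all_perms(K - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[p])
    }
  }
  out
}

## component-indexed column bookkeeping: names like "w.2", "alpha.1", "beta0.2"
component_index <- function(nm) {
  suf <- regmatches(nm, regexpr("\\.[0-9]+$", nm))
  idx <- rep(NA_integer_, length(nm))
  has <- grepl("\\.[0-9]+$", nm)
  idx[has] <- as.integer(sub("^\\.", "", regmatches(nm, regexpr("\\.[0-9]+$", nm))))
  idx
}

#' Undo label switching by pivot reordering
#'
#' The mixture likelihood is invariant under permutation of component
#' labels, so raw chains can switch labels mid-run and corrupt
#' per-component summaries.  This relabels every stored draw by the
#' permutation that best aligns its component-indexed block with a pivot
#' (default: the approximate MAP draw, [map_draw()]).  Alignment is scored
#' as the squared distance between the permuted draw and the pivot after
#' standardising each column by its posterior spread, so large-magnitude
#' coefficients do not dominate.  Per-draw log posterior and log
#' likelihood are untouched (both are permutation invariant).
#'
#' @param chain a [posterior_chain()] whose component-indexed columns are
#'   suffixed `.1`, `.2`, ... (e.g. `alpha.1`, `beta0.2`, `w.1`); columns
#'   without a suffix are shared parameters and left alone.
#' @param K number of components.
#' @param pivot named draw to align to; defaults to [map_draw()] of
#'   `chain`.
#' @return a relabelled [posterior_chain()].
#' @export
reorder_chain <- function(chain, K, pivot = NULL) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (K == 1L) return(chain)
  nm <- chain$parameter_names
  cidx <- component_index(nm)
  if (!any(!is.na(cidx))) stop("chain has no component-indexed columns ('name.m')")
  if (!setequal(stats::na.omit(unique(cidx)), seq_len(K))) {
    stop("component suffixes do not match K")
  }
  if (is.null(pivot)) pivot <- map_draw(chain)
  base <- sub("\\.[0-9]+$", "", nm)
  comp_cols <- lapply(seq_len(K), function(m) which(!is.na(cidx) & cidx == m))
  ## columns must line up across components in the same base-name order
  base1 <- base[comp_cols[[1L]]]
  comp_cols <- lapply(seq_len(K), function(m) {
    cols <- comp_cols[[m]]
    cols[match(base1, base[cols])]
  })
  if (any(vapply(comp_cols, function(cc) any(is.na(cc)), logical(1)))) {
    stop("malformed block structure: components expose different parameters")
  }
  spread <- apply(chain$draws, 2, stats::sd)
  spread[!is.finite(spread) | spread < 1e-12] <- 1
  perms <- all_perms(K)
  allcols <- unlist(comp_cols)
  pivot_v <- pivot[allcols]; sd_v <- spread[allcols]
  draws <- chain$draws
  ## score every permutation for all draws at once: relabelling by perm p
  ## takes label m's block from original component p[m]
  scores <- vapply(perms, function(p) {
    cols <- unlist(comp_cols[p])
    Z <- sweep(draws[, cols, drop = FALSE], 2, pivot_v)
    rowSums(sweep(Z, 2, sd_v, `/`)^2)
  }, numeric(nrow(draws)))
  scores <- matrix(scores, nrow = nrow(draws))
  best <- max.col(-scores, ties.method = "first")
  blk0 <- draws[, allcols, drop = FALSE]
  B <- length(base1)
  for (pi in seq_along(perms)) {
    rows <- which(best == pi)
    p <- perms[[pi]]
    if (identical(p, seq_len(K)) || length(rows) == 0L) next
    ## positions of component p[m]'s block inside blk0
    pos <- unlist(lapply(p, function(m) (m - 1L) * B + seq_len(B)))
    draws[rows, allcols] <- blk0[rows, pos, drop = FALSE]
  }
  posterior_chain(draws, nm, chain$log_posterior, chain$log_likelihood,
                  chain$accept_rate)
}

## log prior for mixture parameters (weights + shapes + coefs)
mixture_logprior <- function(w, alphas, coefs, prior, intercept_only) {
  if (any(alphas <= 0) || any(w <= 0)) return(-Inf)
  lp <- sum((prior$phi - 1) * log(w)) +
    sum(stats::dgamma(alphas, prior$u_alpha, rate = prior$v_alpha, log = TRUE))
  if (intercept_only && prior$gamma_prior) {
    lp <- lp + sum(stats::dgamma(exp(coefs[, 1L]), prior$u_gamma,
                                 rate = prior$v_gamma, log = TRUE) + coefs[, 1L])
  } else {
    lp <- lp + sum(stats::dnorm(coefs, 0, sqrt(prior$sigma2_beta), log = TRUE))
  }
  lp
}

#' Fit the Bayesian Weibull mixture model
#'
#' Gibbs sampler with latent allocations: memberships `Z` from their full
#' conditional ([allocation_step()]), weights from the conjugate Dirichlet
#' update ([weight_update()]), each component's `log(alpha_m)` by slice
#' sampling and each coefficient block by adaptive random-walk Metropolis
#' on the complete-data conditional.  The stored per-draw log-likelihood
#' is the observed-data likelihood (marginal over `Z`), which feeds the
#' BIC; the stored log posterior is observed-data likelihood plus prior,
#' both invariant under relabelling.  A reordered view of the chain
#' (MAP-pivot relabelling, [reorder_chain()]) is attached as
#' `$chain_reordered`.
#'
#' @param data a [survival_dataset()] with at least `K` subjects and one
#'   event.
#' @param K fixed number of mixture components (default 2).
#' @param prior a [mixture_prior()].
#' @param config a [chain_config()].
#' @param empty_warn_frac warn if any component is empty for more than
#'   this fraction of iterations.
#' @return object of class `mixture_fit`/`survbma_fit`; chain columns are
#'   `w.m`, `alpha.m`, `beta<j>.m`.
#' @export
fit_mixture <- function(data, K = 2L, prior = mixture_prior(),
                        config = chain_config(), empty_warn_frac = 0.2) {
  stopifnot(inherits(data, "survival_dataset"))
  K <- as.integer(K)
  n <- n_subjects(data)
  if (n < K) stop("need at least K subjects")
  if (event_count(data) < 1L) stop("refusing to fit a dataset with zero events")
  if (!is.null(config$seed)) set.seed(config$seed)
  p1 <- ncol(data$X)
  X <- data$X; tm <- data$time; lt <- log(tm); dl <- data$status
  intercept_only <- p1 == 1L

  ## --- initial state: split subjects by follow-up time quantiles
  z <- if (K == 1L) rep.int(1L, n) else {
    as.integer(cut(rank(tm, ties.method = "first"),
                   breaks = K, labels = FALSE))
  }
  la <- rep(0, K)                       # log alpha_m
  B <- matrix(0, K, p1)                 # coefficients, rows = components
  for (m in seq_len(K)) {
    idx <- z == m
    d_m <- max(1, sum(dl[idx]))
    B[m, 1L] <- log(d_m / sum(tm[idx]))
  }
  w <- (tabulate(z, K) + prior$phi) / (n + K * prior$phi)


  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  ncols <- K + K + K * p1
  nm <- c(paste0("w.", seq_len(K)), paste0("alpha.", seq_len(K)),
          unlist(lapply(seq_len(K), function(m) paste0("beta", 0:(p1 - 1L), ".", m))))
  draws <- matrix(NA_real_, n_keep, ncols)
  lp_out <- numeric(n_keep); ll_out <- numeric(n_keep)
  log_sc <- rep(log(rep_len(config$proposal_scales, 1L)), K)  # per-component beta block
  n_acc <- 0L; n_prop <- 0L; empty_iters <- 0L
  keep_i <- 0L

  ## inlined allocation conditional: delta*(log a + (a-1) lt + lam) - H + log w
  alloc_fast <- function(w, la, B) {
    L <- matrix(NA_real_, n, K)
    lw <- log(w)
    for (m in seq_len(K)) {
      a <- exp(la[m])
      lam <- drop(X %*% B[m, ])
      L[, m] <- dl * (la[m] + (a - 1) * lt + lam) - exp(a * lt + lam) + lw[m]
    }
    mx <- L[, 1L]
    if (K > 1L) for (m in 2:K) mx <- pmax.int(mx, L[, m])
    if (any(!is.finite(mx))) {
      stop("numerical degeneracy: a subject has zero membership mass in every component")
    }
    P <- exp(L - mx)
    sample_categorical_rows(P / rowSums(P))
  }
  lgam_const <- prior$u_alpha * log(prior$v_alpha) - lgamma(prior$u_alpha)

  for (iter in seq_len(config$n_iter)) {
    z <- alloc_fast(w, la, B)
    cnt <- tabulate(z, K)
    if (any(cnt == 0L)) empty_iters <- empty_iters + 1L
    w <- weight_update(z, K, prior$phi)
    for (m in seq_len(K)) {
      ## members' sufficient pieces are extracted once per sweep so the
      ## slice/MH conditionals cost one exp() pass each
      idx <- which(z == m)
      Xm <- X[idx, , drop = FALSE]
      ltm <- lt[idx]; dlm <- dl[idx]
      sdlm <- sum(dlm); sdlmlt <- sum(dlm * ltm)
      beta_m <- B[m, ]
      lam_m <- drop(Xm %*% beta_m)
      sdlmlam <- sum(dlm * lam_m)
      beta_pr <- function(beta) {
        if (intercept_only && prior$gamma_prior) {
          stats::dgamma(exp(beta[1L]), prior$u_gamma,
                        rate = prior$v_gamma, log = TRUE) + beta[1L]
        } else {
          sum(stats::dnorm(beta, 0, sqrt(prior$sigma2_beta), log = TRUE))
        }
      }
      ## slice on log alpha_m | members, beta_m
      cond_a <- function(v) {
        a <- exp(v)
        lgam_const + (prior$u_alpha - 1) * v - prior$v_alpha * a + v +
          sdlm * v + (a - 1) * sdlmlt + sdlmlam - sum(exp(a * ltm + lam_m))
      }
      la[m] <- slice_step(cond_a, la[m], width = 1)
      a_m <- exp(la[m])
      ## random-walk MH on beta_m | members, alpha_m
      ll_cur <- sdlm * la[m] + (a_m - 1) * sdlmlt + sdlmlam -
        sum(exp(a_m * ltm + lam_m))
      prop <- beta_m + stats::rnorm(p1, 0, exp(log_sc[m]))
      lam_p <- drop(Xm %*% prop)
      ll_p <- sdlm * la[m] + (a_m - 1) * sdlmlt + sum(dlm * lam_p) -
        sum(exp(a_m * ltm + lam_p))
      n_prop <- n_prop + 1L
      acc <- is.finite(ll_p) &&
        log(stats::runif(1)) < (ll_p + beta_pr(prop)) - (ll_cur + beta_pr(beta_m))
      if (acc) {
        B[m, ] <- prop
        n_acc <- n_acc + 1L
      }
      if (config$adapt && iter <= config$burn_in) {
        log_sc[m] <- adapt_scale(log_sc[m], acc, config$target_accept, iter)
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      params <- structure(list(K = K, weights = w, shapes = exp(la),
                               coefs = B), class = "mixture_params")
      ll <- mixture_loglik(data, params)
      draws[keep_i, ] <- c(w, exp(la), c(t(B)))
      ll_out[keep_i] <- ll
      lp_out[keep_i] <- ll + mixture_logprior(w, exp(la), B, prior,
                                              intercept_only)
    }
  }
  if (empty_iters / config$n_iter > empty_warn_frac) {
    warning(sprintf("a mixture component was empty in %.0f%% of iterations; K may be too large",
                    100 * empty_iters / config$n_iter))
  }
  chain <- posterior_chain(draws, nm, lp_out, ll_out,
                           accept_rate = c(beta_blocks = n_acc / n_prop))
  chain_reordered <- reorder_chain(chain, K)

  d_s <- K + K * p1 + (K - 1L)
  unpack <- function(par) {
    w <- par[seq_len(K)]
    a <- par[K + seq_len(K)]
    Bm <- matrix(par[2L * K + seq_len(K * p1)], nrow = K, byrow = TRUE)
    mixture_params(w / sum(w), a, Bm)
  }
  structure(list(model = "mixture", K = K, chain = chain,
                 chain_reordered = chain_reordered, data = data,
                 prior = prior, d_s = d_s,
                 empty_fraction = empty_iters / config$n_iter,
                 loglik_fn = function(par) mixture_loglik(data, unpack(par)),
                 to_unconstrained = function(par) {
                   w <- par[seq_len(K)]
                   c(log(w[-K] / w[K]), log(par[K + seq_len(K)]),
                     par[2L * K + seq_len(K * p1)])
                 },
                 from_unconstrained = function(u) {
                   lr <- u[seq_len(K - 1L)]
                   ew <- c(exp(lr), 1); w <- ew / sum(ew)
                   c(w, exp(u[K - 1L + seq_len(K)]),
                     u[2L * K - 1L + seq_len(K * p1)])
                 }),
            class = c("mixture_fit", "survbma_fit"))
}

#' @rdname predictive_draws
#' @export
predictive_draws.mixture_fit <- function(fit, x, n_draws_out,
                                         use_reordered = FALSE, ...) {
  if (n_draws_out == 0L) return(numeric(0))
  ch <- if (use_reordered) fit$chain_reordered else fit$chain
  dr <- ch$draws
  K <- fit$K; p1 <- ncol(fit$data$X)
  idx <- sample.int(nrow(dr), n_draws_out, replace = TRUE)
  W <- dr[idx, seq_len(K), drop = FALSE]
  comp <- sample_categorical_rows(W / rowSums(W))
  a <- dr[cbind(idx, K + comp)]
  lam <- numeric(n_draws_out)
  for (m in seq_len(K)) {
    sel <- comp == m
    if (!any(sel)) next
    Bm <- dr[idx[sel], 2L * K + (m - 1L) * p1 + seq_len(p1), drop = FALSE]
    lam[sel] <- drop(Bm %*% x)
  }
  u <- stats::runif(n_draws_out)
  (-log(u) * exp(-lam))^(1 / a)
}
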
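#' Weibull law in the log-scale parameterisation
#'
#' Container for a Weibull distribution parameterised by shape `alpha` and
#' log-scale `lambda = log(gamma)`, so that the hazard is
#' `h(t) = alpha * t^(alpha-1) * exp(lambda)` and the survival function is
#' `S(t) = exp(-t^alpha * exp(lambda))`.  This parameterisation makes the log
#' hazard linear in `log(t)` and leaves `lambda` unconstrained, which is why
#' covariates enter the regression models through `lambda`.
#'
#' @param shape positive shape parameter `alpha`.
#' @param log_scale real log-scale `lambda = log(gamma)`.
#' @return An object of class `weibull_law`.
#' @examples
#' law <- weibull_law(shape = 2, log_scale = 0.5)
#' weibull_hazard(1.3, law)
#' @export
weibull_law <- function(shape, log_scale) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0) {
    stop("`shape` (alpha) must be a single positive finite number")
  }
  if (!is.numeric(log_scale) || length(log_scale) != 1L ||
      !is.finite(log_scale)) {
    stop("`log_scale` (lambda) must be a single finite number")
  }
  structure(list(shape = shape, log_scale = log_scale),
            class = "weibull_law")
}

#' @export
print.weibull_law <- function(x, ...) {
  cat(sprintf("Weibull law: shape alpha = %g, log-scale lambda = %g (gamma = %g)\n",
              x$shape, x$log_scale, exp(x$log_scale)))
  invisible(x)
}

as_weibull_law <- function(law) {
  if (!inherits(law, "weibull_law")) stop("`law` must be a `weibull_law`")
  law
}

#' Weibull log-density, log-survival and hazard
#'
#' Density `f(t) = alpha t^(alpha-1) e^lambda exp(-t^alpha e^lambda)`,
#' survival `S(t) = exp(-t^alpha e^lambda)` and hazard
#' `h(t) = alpha t^(alpha-1) e^lambda`, all in the log-scale
#' parameterisation (see [weibull_law()]).  The identity
#' `log f = log h + log S` holds exactly.
#'
#' @param t event time(s); strictly positive for the density and hazard,
#'   non-negative for the survival function.
#' @param law a [weibull_law()].
#' @return `weibull_logpdf` and `weibull_logsurv` return log-densities /
#'   log-survival probabilities; `weibull_hazard` returns the hazard rate.
#'   All are vectorised over `t`.
#' @export
weibull_logpdf <- function(t, law) {
  law <- as_weibull_law(law)
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be positive and finite")
  log(law$shape) + (law$shape - 1) * log(t) + law$log_scale -
    t^law$shape * exp(law$log_scale)
}

#' @rdname weibull_logpdf
#' @export
weibull_logsurv <- function(t, law) {
  law <- as_weibull_law(law)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be non-negative and finite")
  -t^law$shape * exp(law$log_scale)
}

#' @rdname weibull_logpdf
#' @export
weibull_hazard <- function(t, law) {
  law <- as_weibull_law(law)
  if (any(!is.finite(t)) || any(t <= 0)) stop("`t` must be positive and finite")
  law$shape * t^(law$shape - 1) * exp(law$log_scale)
}

#' Inverse-CDF sampler for the Weibull law
#'
#' Maps a uniform(0,1) variate `u` to the time `t` with `S(t) = u`, i.e.
#' `t = (-log(u) * exp(-lambda))^(1/alpha)`.  Used for posterior predictive
#' simulation; the round trip `weibull_logsurv(sample_weibull(law, u)) ==
#' log(u)` holds to machine precision.
#'
#' @param law a [weibull_law()].
#' @param u uniform(0,1) variate(s), strictly inside the unit interval.
#' @return positive time(s), vectorised over `u`.
#' @export
sample_weibull <- function(law, u) {
  law <- as_weibull_law(law)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly in (0, 1)")
  }
  (-log(u) * exp(-law$log_scale))^(1 / law$shape)
}

## vectorised internal kernels used by the model likelihoods: lambda may vary
## per subject, positivity of t is the caller's responsibility.
wb_logpdf_v <- function(t, alpha, lambda) {
  log(alpha) + (alpha - 1) * log(t) + lambda - t^alpha * exp(lambda)
}
wb_logsurv_v <- function(t, alpha, lambda) {
  -t^alpha * exp(lambda)
}

#' Right-censored survival dataset
#'
#' Validating container for right-censored survival data: one row per subject
#' with a positive follow-up time, a 0/1 event indicator (1 = observed
#' failure, 0 = right-censored; censored subjects are treated as event-free
#' regardless of observation time), a covariate matrix whose first column is
#' an intercept of ones, and an optional categorical phenotype label used for
#' stratified refits.
#'
#' @param time positive follow-up times (zero times are rejected).
#' @param status 0/1 event indicators.
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (WITHOUT the intercept; one is prepended).  `NULL` gives an
#'   intercept-only design.
#' @param phenotype optional factor (or vector coercible to factor) of
#'   per-subject phenotype labels.
#' @param time_unit metadata string carried along, never used in computation.
#' @return An object of class `survival_dataset` with elements `time`,
#'   `status`, `X` (n x (p+1) matrix including the intercept column),
#'   `covariate_names`, `phenotype`, `time_unit`.
#' @examples
#' d <- survival_dataset(time = c(1, 2, 3), status = c(1, 0, 1))
#' event_count(d)
#' @export
survival_dataset <- function(time, status, covariates = NULL,
                             phenotype = NULL, time_unit = "years") {
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (n == 0L) stop("dataset must contain at least one record")
  if (length(status) != n) stop("`time` and `status` lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all follow-up times must be positive (t = 0 records are rejected)")
  }
  if (any(is.na(status)) || !all(status %in% c(0, 1))) {
    stop("`status` must be 0 (censored) or 1 (event)")
  }
  if (!is.null(covariates) && NCOL(covariates) == 0L) covariates <- NULL
  if (is.null(covariates)) {
    X <- matrix(1, nrow = n, ncol = 1L)
    colnames(X) <- "intercept"
  } else {
    X0 <- as.matrix(covariates)
    storage.mode(X0) <- "double"
    if (nrow(X0) != n) stop("`covariates` must have one row per subject")
    if (any(!is.finite(X0))) stop("covariates must be finite")
    if (is.null(colnames(X0))) {
      colnames(X0) <- paste0("x", seq_len(ncol(X0)))
    }
    X <- cbind(intercept = 1, X0)
  }
  if (anyDuplicated(colnames(X))) stop("covariate names must be unique")
  if (!is.null(phenotype)) {
    phenotype <- as.factor(phenotype)
    if (length(phenotype) != n) stop("`phenotype` must have one label per subject")
  }
  structure(list(time = time, status = status, X = X,
                 covariate_names = colnames(X), phenotype = phenotype,
                 time_unit = time_unit),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Right-censored survival dataset: %d subjects, %d events (%.1f%%), %d covariate column(s) incl. intercept\n",
              length(x$time), event_count(x),
              100 * event_count(x) / length(x$time), ncol(x$X)))
  if (!is.null(x$phenotype)) {
    cat("  phenotype levels:", paste(levels(x$phenotype), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of observed events
#'
#' The count of uncensored observations, `sum(status)`.  This is the `n`
#' that enters the BIC penalty for survival models (see [compute_bic()]).
#'
#' @param data a [survival_dataset()].
#' @return non-negative integer.
#' @export
event_count <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  as.integer(sum(data$status))
}

#' Number of subjects
#' @param data a [survival_dataset()].
#' @return positive integer.
#' @export
n_subjects <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  length(data$time)
}

#' Subset a survival dataset
#'
#' @param data a [survival_dataset()].
#' @param idx integer or logical index of records to keep.
#' @return a [survival_dataset()] restricted to `idx`.
#' @export
subset_dataset <- function(data, idx) {
  stopifnot(inherits(data, "survival_dataset"))
  survival_dataset(time = data$time[idx], status = data$status[idx],
                   covariates = data$X[idx, -1L, drop = FALSE],
                   phenotype = if (is.null(data$phenotype)) NULL else
                     droplevels(data$phenotype[idx]),
                   time_unit = data$time_unit)
}

#' Read a survival dataset from a delimited file
#'
#' Expects a header row with columns `time` and `status` (1 = event,
#' 0 = censored), an optional `phenotype` column, and any remaining numeric
#' columns treated as covariates (standardised scores are expected but not
#' enforced).  Field separator is sniffed from the extension (`.tsv` ->
#' tab, otherwise comma).
#'
#' @param path path to a CSV/TSV file.
#' @return a [survival_dataset()].
#' @export
read_survival_data <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("time", "status") %in% names(df))) {
    stop("dataset file must contain `time` and `status` columns")
  }
  phen <- if ("phenotype" %in% names(df)) df$phenotype else NULL
  covar_cols <- setdiff(names(df), c("time", "status", "phenotype"))
  covs <- if (length(covar_cols)) df[covar_cols] else NULL
  survival_dataset(time = df$time, status = df$status, covariates = covs,
                   phenotype = phen)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_data()]: writes `time`, `status`, the covariate
#' columns (without the intercept) and, if present, `phenotype`.
#'
#' @param data a [survival_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(time = data$time, status = data$status,
                   check.names = FALSE)
  if (ncol(data$X) > 1L) {
    df <- cbind(df, as.data.frame(data$X[, -1L, drop = FALSE]))
  }
  if (!is.null(data$phenotype)) df$phenotype <- as.character(data$phenotype)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kaplan-Meier product-limit estimator
#'
#' Product-limit estimate of the survival curve, delegated to
#' [survival::survfit()].  Events at a tied time are processed before
#' censorings at the same time (the standard convention); censored subjects
#' leave the risk set without a drop in the curve.
#'
#' @param data a [survival_dataset()].
#' @return An object of class `km_estimate`: a data.frame-backed step
#'   function with columns `time`, `n_risk`, `n_event`, `surv`, and an
#'   evaluator usable through [km_surv_at()].
#' @export
kaplan_meier <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  fit <- survival::survfit(survival::Surv(data$time, data$status) ~ 1,
                           conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  structure(list(table = tab, n = length(data$time)), class = "km_estimate")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous evaluation of the product-limit step function:
#' `S(t) = 1` before the first event time.
#'
#' @param km a `km_estimate` from [kaplan_meier()].
#' @param t time(s) at which to evaluate.
#' @return survival probabilities, vectorised over `t`.
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  tab <- km$table[km$table$n_event > 0, , drop = FALSE]
  if (nrow(tab) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, tab$time)
  c(1, tab$surv)[idx + 1L]
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate on %d subjects (%d distinct times)\n",
              x$n, nrow(x$table)))
  invisible(x)
}
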
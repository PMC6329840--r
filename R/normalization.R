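#' Unique values for distribution fitting
#'
#' Ties are removed only for the purpose of fitting the normalizing
#' distribution to the present-period sample; the fitted transform is then
#' applied to the full field, so cells sharing a raw value always share a
#' normalized score.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Sorted unique values.
#' @export
dedup_for_fit <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to fit")
  sort(unique(values))
}

#' Fit a Johnson-system distribution for normalization
#'
#' Fits the Johnson family branch appropriate to the variable's support and
#' returns the fitted CDF parameters used to map raw values to (0, 1)
#' scores:
#'
#' * `support = "nonnegative"`: the log-normal-type branch (S_L) with lower
#'   bound pinned at 0, `z = gamma + delta * log(x)` — used for population
#'   density, whose domain is \[0, +Inf); zeros sit at CDF 0 and are excluded
#'   from the fit sample.
#' * `support = "unit"`: the bounded branch (S_B) with support pinned to
#'   (0, 1), `z = gamma + delta * log(x / (1 - x))` — used for the
#'   vulnerability proxy 1-HDI, so any projected value keeps a valid score.
#'
#' With both bounds pinned the family has two free parameters (gamma,
#' delta), fitted by exact maximum likelihood on the transformed scale.
#' Goodness of fit is assessed by a Kolmogorov-Smirnov test on the
#' (tie-free) fit sample; rejection at `ks_alpha` sets the `ks_reject` flag
#' and raises a warning but does not fail the fit.
#'
#' @param values Raw present-period sample (ties removed internally via
#'   [dedup_for_fit()]).
#' @param support `"nonnegative"` or `"unit"`.
#' @param min_unique Minimum number of unique positive (interior) values
#'   required (default 30).
#' @param ks_alpha Significance level of the KS goodness-of-fit warning.
#' @return Object of class `johnson_fit`: `family` ("SL"/"SB"), `gamma`,
#'   `delta`, `xi_j`, `lambda_j` (pinned bounds), `n_fit`, `ks_p`,
#'   `ks_reject`.
#' @export
fit_johnson <- function(values, support = c("nonnegative", "unit"),
                        min_unique = 30, ks_alpha = 0.05) {
  support <- match.arg(support)
  u <- dedup_for_fit(values)
  if (support == "nonnegative") {
    if (any(u < 0)) stop("negative values under nonnegative support")
    sample_fit <- u[u > 0]
    z <- log(sample_fit)
    family <- "SL"; xi_j <- 0; lambda_j <- 1
  } else {
    if (any(u <= 0 | u >= 1))
      stop("values outside (0, 1) under unit support")
    sample_fit <- u
    z <- stats::qlogis(sample_fit)
    family <- "SB"; xi_j <- 0; lambda_j <- 1
  }
  if (length(sample_fit) < min_unique)
    stop(sprintf("need at least %d unique values to fit (got %d)",
                 min_unique, length(sample_fit)))
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) stop("degenerate sample: zero spread")
  delta <- 1 / s
  gamma <- -mean(z) * delta
  fit <- structure(list(family = family, gamma = gamma, delta = delta,
                        xi_j = xi_j, lambda_j = lambda_j,
                        n_fit = length(sample_fit),
                        ks_p = NA_real_, ks_reject = NA),
                   class = "johnson_fit")
  ks <- suppressWarnings(
    stats::ks.test(sample_fit, function(q) johnson_cdf(fit, q)))
  fit$ks_p <- ks$p.value
  fit$ks_reject <- ks$p.value < ks_alpha
  if (fit$ks_reject)
    warning(sprintf("Johnson %s fit rejected by KS test (p = %.3g)",
                    family, ks$p.value))
  fit
}

#' Fitted Johnson CDF
#'
#' Evaluates the fitted cumulative distribution function; values at or below
#' the lower bound map to 0 and (for the bounded branch) values at or above
#' the upper bound map to 1, so out-of-support projections saturate instead
#' of failing.
#'
#' @param fit A [fit_johnson()] object.
#' @param x Raw values.
#' @return CDF values in \[0, 1\] (NA passed through).
#' @export
johnson_cdf <- function(fit, x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (fit$family == "SL") {
    lo <- ok & x <= 0
    inr <- ok & x > 0
    out[lo] <- 0
    out[inr] <- stats::pnorm(fit$gamma + fit$delta * log(x[inr]))
  } else {
    out[ok & x <= 0] <- 0
    out[ok & x >= 1] <- 1
    inr <- ok & x > 0 & x < 1
    out[inr] <- stats::pnorm(fit$gamma + fit$delta * stats::qlogis(x[inr]))
  }
  out
}

#' Normalize a gridded field through a fitted present-period CDF
#'
#' Maps raw values to uniform (0, 1) scores with the CDF fitted to the
#' present period of the same variable; projections are transformed through
#' the present-period fit so present and future share one scale. The map is
#' monotone, sends 0 (zero population, or 1-HDI of 0) to score 0, and gives
#' equal raw values equal scores. Missing cells stay missing.
#'
#' @param raw Numeric vector or matrix of raw values.
#' @param fit The present-period [fit_johnson()] of the same variable.
#' @return Scores with the shape of `raw`.
#' @export
normalize_field <- function(raw, fit) {
  stopifnot(inherits(fit, "johnson_fit"))
  out <- johnson_cdf(fit, as.vector(raw))
  if (is.matrix(raw)) dim(out) <- dim(raw)
  out
}
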
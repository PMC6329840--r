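#' Decadal block maxima of an annual index series
#'
#' @param x Numeric vector of annual values (or matrix `years x ncell`).
#' @param block_length Block length in years (default 10).
#' @return Vector of `length(x)/block_length` maxima (or matrix
#'   `nblocks x ncell`).
#' @export
block_maxima <- function(x, block_length = 10) {
  if (is.matrix(x)) return(apply(x, 2, block_maxima, block_length = block_length))
  n <- length(x)
  if (n == 0L || n %% block_length != 0)
    stop("series length must be a positive multiple of the block length")
  nb <- n %/% block_length
  vapply(seq_len(nb), function(k)
    max(x[((k - 1L) * block_length + 1L):(k * block_length)]), numeric(1))
}

#' Sample L-moments
#'
#' First two L-moments and the L-skewness, from unbiased probability-weighted
#' moments of the ordered sample.
#'
#' @param x Numeric sample (n >= 3).
#' @return List with `l1`, `l2`, `t3`.
#' @export
sample_lmoments <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 3) stop("need at least 3 values for L-moments")
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((i - 1) / (n - 1) * x) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n
  l2 <- 2 * b1 - b0
  l3 <- 6 * b2 - 6 * b1 + b0
  list(l1 = b0, l2 = l2, t3 = l3 / l2)
}

.euler_gamma <- 0.57721566490153286

#' GEV distribution functions
#'
#' Distribution, quantile and log-density of the generalized extreme value
#' distribution in the climatological parameterization with shape `shape`
#' (xi): `shape = 0` is Gumbel, `shape > 0` Frechet-type (heavy upper tail).
#' CDF: `exp(-t(q))` with `t = (1 + shape*(q-loc)/scale)^(-1/shape)` (Gumbel
#' limit `t = exp(-(q-loc)/scale)`).
#'
#' @param q,p Quantiles / probabilities.
#' @param loc,scale,shape Location, scale (> 0), shape parameters.
#' @return `pgev`: probabilities; `qgev`: quantiles; `dgev_log`: log-density.
#' @export
pgev <- function(q, loc, scale, shape) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-12) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- ifelse(t > 0, exp(-t^(-1 / shape)),
                ifelse(shape > 0, 0, 1))
  out
}

#' @rdname pgev
#' @export
qgev <- function(p, loc, scale, shape) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  y <- -log(p)
  if (abs(shape) < 1e-12) return(loc - scale * log(y))
  loc + scale / shape * (y^(-shape) - 1)
}

#' @rdname pgev
#' @param x Sample values (for the log-density).
#' @export
dgev_log <- function(x, loc, scale, shape) {
  if (!is.finite(loc) || !is.finite(scale) || !is.finite(shape) || scale <= 0)
    return(rep(-Inf, length(x)))
  z <- (x - loc) / scale
  if (abs(shape) < 1e-12) return(-log(scale) - z - exp(-z))
  t <- 1 + shape * z
  if (any(!is.finite(t)) || any(t <= 0)) return(rep(-Inf, length(x)))
  -log(scale) - (1 + 1 / shape) * log(t) - t^(-1 / shape)
}

#' Fit a GEV by L-moments with a non-negative shape constraint
#'
#' Solves the standard GEV L-moment matching equations from the sample
#' L-moments. The shape is constrained to the Frechet/Gumbel branch
#' (`shape >= 0`): when the unconstrained solution has a negative shape
#' (bounded upper tail), the sample is re-fit as a Gumbel distribution,
#' reflecting the assumption that block-maximum heatwave magnitudes are not
#' bounded above.
#'
#' @param x Block-maxima sample.
#' @param min_blocks Minimum sample size (default 20 blocks).
#' @return List of class `gev_params`: `loc`, `scale`, `shape`, `method`
#'   (`"lmom"` or `"lmom-gumbel"`), `n_blocks`.
#' @export
fit_gev_lmoments <- function(x, min_blocks = 20) {
  x <- x[!is.na(x)]
  if (length(x) < min_blocks)
    stop(sprintf("need at least %d blocks to fit (got %d)",
                 min_blocks, length(x)))
  lm <- sample_lmoments(x)
  if (!is.finite(lm$t3) || lm$l2 <= 0)
    stop("degenerate block-maxima sample (zero L-scale)")
  # Hosking's shape k (= -shape here): rational approximation from t3
  cc <- 2 / (3 + lm$t3) - log(2) / log(3)
  k <- 7.8590 * cc + 2.9554 * cc^2
  if (k <= -1)
    stop("L-skewness outside the range of a finite-mean GEV fit")
  if (k >= 0 || abs(k) < 1e-9) {
    # unconstrained shape would be <= 0 on this branch => Gumbel re-fit
    scale <- lm$l2 / log(2)
    loc <- lm$l1 - .euler_gamma * scale
    shape <- 0
    method <- "lmom-gumbel"
  } else {
    gk <- gamma(1 + k)
    scale <- lm$l2 * k / ((1 - 2^(-k)) * gk)
    loc <- lm$l1 - scale * (1 - gk) / k
    shape <- -k
    method <- "lmom"
  }
  structure(list(loc = loc, scale = scale, shape = shape,
                 method = method, n_blocks = length(x)),
            class = "gev_params")
}

#' Return level for a given return period
#'
#' The level whose per-block (per-decade) exceedance probability is `1/T`.
#' Return periods are counted in blocks of the fitted maxima, i.e. decades:
#' the "500-year" heatwave is the level exceeded with probability 0.002 in
#' any one decade. The conventional "year" label is kept in names only.
#'
#' @param params A `gev_params` fit.
#' @param T Return period in blocks (> 1).
#' @return The return level.
#' @export
return_level <- function(params, T) {
  if (T <= 1) stop("return period must exceed 1 block")
  qgev(1 - 1 / T, params$loc, params$scale, params$shape)
}

#' Per-block exceedance probability of a level
#'
#' @param params A `gev_params` fit.
#' @param level Level(s) to exceed.
#' @return `1 - F_GEV(level)`, in \[0, 1\].
#' @export
exceedance_probability <- function(params, level) {
  1 - pgev(level, params$loc, params$scale, params$shape)
}

#' Hazard probability of present-climate return levels under another state
#'
#' For each cell, the probability (per decade) that the index under the
#' future fit exceeds the present-climate T-block return level. Under the
#' present state itself this is `1/T` by construction.
#'
#' @param present,future Lists of `gev_params` (one per cell; NULL entries
#'   are masked cells).
#' @param T Return period in blocks (default 500).
#' @return Numeric vector of probabilities (NA at masked cells).
#' @export
hazard_under_state <- function(present, future, T = 500) {
  stopifnot(length(present) == length(future))
  vapply(seq_along(present), function(i) {
    if (is.null(present[[i]]) || is.null(future[[i]])) return(NA_real_)
    exceedance_probability(future[[i]], return_level(present[[i]], T))
  }, numeric(1))
}

# Maximum-likelihood GEV fit under shape >= 0, initialized from the L-moment
# fit; used by the profile-likelihood interval.
gev_fit_mle <- function(x, shape_max = 1.5) {
  start <- tryCatch(fit_gev_lmoments(x, min_blocks = 5),
                    error = function(e) NULL)
  if (is.null(start))
    start <- list(loc = mean(x), scale = stats::sd(x), shape = 0.1)
  nll <- function(par) {
    ll <- dgev_log(x, par[1], exp(par[2]), par[3])
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v   # keep L-BFGS-B on finite ground
  }
  fit <- suppressWarnings(
    stats::optim(c(start$loc, log(max(start$scale, 1e-8)),
                   max(start$shape, 1e-6)),
                 nll, method = "L-BFGS-B",
                 lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, shape_max)))
  list(loc = fit$par[1], scale = exp(fit$par[2]), shape = fit$par[3],
       loglik = -fit$value, convergence = fit$convergence)
}

# Profile log-likelihood of the T-block return level at a fixed level z:
# reparameterize (loc, scale, shape) -> (z_T, scale, shape) and maximize over
# the nuisance parameters with shape >= 0.
.profile_loglik_z <- function(x, z, T, start, shape_max = 1.5) {
  yT <- -log(1 - 1 / T)
  nll <- function(par) {
    scale <- exp(par[1]); shape <- par[2]
    loc <- if (shape < 1e-9) z + scale * log(yT)
           else z - scale / shape * (yT^(-shape) - 1)
    v <- -sum(dgev_log(x, loc, scale, shape))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- tryCatch(
    suppressWarnings(
      stats::optim(c(log(max(start$scale, 1e-8)), max(start$shape, 1e-6)),
                   nll, method = "L-BFGS-B",
                   lower = c(-Inf, 0), upper = c(Inf, shape_max))),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  -fit$value
}

#' Profile-likelihood confidence interval for a return level
#'
#' Confidence interval for the T-block return level based on the profile
#' likelihood of `z_T` under the `shape >= 0` constraint: the interval is the
#' set of levels whose profile deviance from the constrained maximum
#' likelihood does not exceed the chi-squared(1) quantile. `alpha = 1`
#' collapses the interval onto the maximum-likelihood point estimate.
#'
#' @param x Block-maxima sample (>= 20 blocks).
#' @param T Return period in blocks.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @param min_blocks Minimum sample size.
#' @return List with `lower`, `upper`, `estimate` (ML return level),
#'   `converged` (logical; on failure the interval is NA).
#' @export
confidence_interval <- function(x, T, alpha = 0.05, min_blocks = 20) {
  x <- x[!is.na(x)]
  if (length(x) < min_blocks)
    stop(sprintf("need at least %d blocks (got %d)", min_blocks, length(x)))
  mle <- tryCatch(gev_fit_mle(x), error = function(e) NULL)
  if (is.null(mle) || !is.finite(mle$loglik))
    return(list(lower = NA_real_, upper = NA_real_, estimate = NA_real_,
                converged = FALSE))
  z_hat <- qgev(1 - 1 / T, mle$loc, mle$scale, mle$shape)
  target <- stats::qchisq(1 - alpha, df = 1)
  if (target == 0)
    return(list(lower = z_hat, upper = z_hat, estimate = z_hat,
                converged = TRUE))
  dev <- function(z) {
    d <- 2 * (mle$loglik - .profile_loglik_z(x, z, T, mle))
    if (!is.finite(d)) 1e10 else d    # infinite deviance = impossible level
  }

  find_bound <- function(direction) {
    step <- max(mle$scale, 1e-3)
    z0 <- z_hat
    for (i in 1:60) {
      z1 <- z_hat + direction * step
      d <- dev(z1)
      if (is.finite(d) && d >= target) {
        r <- tryCatch(
          stats::uniroot(function(z) dev(z) - target,
                         lower = min(z0, z1), upper = max(z0, z1),
                         tol = 1e-6 * max(1, abs(z_hat))),
          error = function(e) NULL)
        return(if (is.null(r)) NA_real_ else r$root)
      }
      if (is.finite(d)) z0 <- z1
      step <- step * 1.6
    }
    NA_real_
  }
  lower <- find_bound(-1)
  upper <- find_bound(1)
  list(lower = lower, upper = upper, estimate = z_hat,
       converged = is.finite(lower) && is.finite(upper))
}

#' Anderson-Darling statistic against a fitted GEV
#'
#' @param x Sample.
#' @param params A `gev_params` fit (or any list with loc/scale/shape).
#' @return The A-squared statistic.
#' @export
ad_statistic <- function(x, params) {
  n <- length(x)
  u <- pgev(sort(x), params$loc, params$scale, params$shape)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Parametric-bootstrap Anderson-Darling GEV goodness-of-fit test
#'
#' Tests the null hypothesis that the block maxima follow a GEV with
#' `shape >= 0`, with more weight on the tails than a Kolmogorov-Smirnov
#' test. Because parameters are estimated from the same sample, the null
#' distribution of the statistic is obtained by a parametric bootstrap in
#' which each replicate is re-fitted before its statistic is computed.
#'
#' @param x Block-maxima sample.
#' @param n_boot Bootstrap replicates (default 200).
#' @param min_blocks Minimum sample size for the fit.
#' @return List with `statistic`, `p_value` (NA on a degenerate fit) and the
#'   `fit` used.
#' @export
ad_test_gev <- function(x, n_boot = 200, min_blocks = 20) {
  fit <- tryCatch(fit_gev_lmoments(x, min_blocks), error = function(e) NULL)
  if (is.null(fit))
    return(list(statistic = NA_real_, p_value = NA_real_, fit = NULL))
  a2 <- ad_statistic(x, fit)
  n <- length(x)
  a2_boot <- vapply(seq_len(n_boot), function(b) {
    xb <- qgev(stats::runif(n), fit$loc, fit$scale, fit$shape)
    fb <- tryCatch(fit_gev_lmoments(xb, min_blocks), error = function(e) NULL)
    if (is.null(fb)) return(NA_real_)
    ad_statistic(xb, fb)
  }, numeric(1))
  a2_boot <- a2_boot[is.finite(a2_boot)]
  p <- (1 + sum(a2_boot >= a2)) / (length(a2_boot) + 1)
  list(statistic = a2, p_value = p, fit = fit)
}

#' Fit GEV distributions cell-by-cell
#'
#' Fits [fit_gev_lmoments()] to each column of a block-maxima matrix. Cells
#' with a degenerate series (e.g. all-zero HWMId, zero L-scale) are masked
#' (NULL entry) rather than fitted.
#'
#' @param bm Matrix `nblocks x ncell`.
#' @param min_blocks Minimum blocks per fit.
#' @return List of `gev_params` (NULL for masked cells).
#' @export
fit_gev_cells <- function(bm, min_blocks = 20) {
  lapply(seq_len(ncol(bm)), function(c)
    tryCatch(fit_gev_lmoments(bm[, c], min_blocks), error = function(e) NULL))
}
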
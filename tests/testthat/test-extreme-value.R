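# combinatorial L-moment oracle: direct order-statistic expectations over all
# pairs and triples
lmoments_oracle <- function(x) {
  n <- length(x)
  pairs <- combn(x, 2)
  l2 <- mean(apply(pairs, 2, function(p) max(p) - min(p))) / 2
  triples <- combn(x, 3)
  l3 <- mean(apply(triples, 2, function(t) {
    s <- sort(t); s[3] - 2 * s[2] + s[1]
  })) / 3
  list(l1 = mean(x), l2 = l2, t3 = l3 / l2)
}

test_that("block maxima aggregate complete decades only", {
  expect_length(block_maxima(rnorm(30)), 3)
  x <- c(1:10, 21:30, rep(1, 10))
  expect_equal(block_maxima(x), c(10, 30, 1))
  expect_equal(block_maxima(rep(7, 40)), rep(7, 4))
  expect_error(block_maxima(rnorm(25)), "multiple")
  m <- matrix(rnorm(60), 30, 2)
  bm <- block_maxima(m)
  expect_equal(dim(bm), c(3, 2))
  expect_equal(bm[2, 1], max(m[11:20, 1]))
})

test_that("sample L-moments match the combinatorial oracle", {
  set.seed(13)
  x <- rlnorm(50)
  got <- sample_lmoments(x)
  want <- lmoments_oracle(x)
  expect_equal(got$l1, want$l1, tolerance = 1e-9)
  expect_equal(got$l2, want$l2, tolerance = 1e-9)
  expect_equal(got$t3, want$t3, tolerance = 1e-9)
})

test_that("L-moment GEV fit recovers simulated parameters", {
  set.seed(31)
  x <- qgev(runif(2000), 5, 1.5, 0.2)
  f <- fit_gev_lmoments(x)
  expect_equal(f$loc, 5, tolerance = 0.15)
  expect_equal(f$scale, 1.5, tolerance = 0.15)
  expect_equal(f$shape, 0.2, tolerance = 0.05)
  expect_identical(f$method, "lmom")
})

test_that("negative unconstrained shape falls back to an exact Gumbel fit", {
  set.seed(17)
  x <- qgev(runif(500), 0, 1, -0.3)   # bounded-tail sample
  f <- fit_gev_lmoments(x)
  expect_identical(f$shape, 0)
  expect_identical(f$method, "lmom-gumbel")
  # the fallback equals the Gumbel L-moment solution computed directly
  lm <- sample_lmoments(x)
  expect_equal(f$scale, lm$l2 / log(2))
  expect_equal(f$loc, lm$l1 - 0.57721566490153286 * lm$l2 / log(2))
})

test_that("fitting degenerate or short series errors out", {
  expect_error(fit_gev_lmoments(rep(3, 50)), "degenerate")
  expect_error(fit_gev_lmoments(rnorm(10)), "at least 20")
  expect_silent(fit_gev_lmoments(rnorm(10), min_blocks = 5))
})

test_that("return levels follow the closed forms and invert exactly", {
  gum <- structure(list(loc = 0, scale = 1, shape = 0), class = "gev_params")
  expect_equal(return_level(gum, 500), -log(-log(0.998)))
  fre <- structure(list(loc = 0, scale = 1, shape = 0.2), class = "gev_params")
  expect_equal(return_level(fre, 100),
               (1 / 0.2) * ((-log(0.99))^(-0.2) - 1))
  expect_error(return_level(gum, 1), "exceed 1")

  # inverse-pair property over random valid parameters
  set.seed(23)
  for (r in 1:50) {
    p <- structure(list(loc = runif(1, -10, 10), scale = runif(1, 0.1, 5),
                        shape = runif(1, 0, 0.9)), class = "gev_params")
    T <- runif(1, 1.5, 2000)
    expect_equal(exceedance_probability(p, return_level(p, T)), 1 / T,
                 tolerance = 1e-12)
  }
})

test_that("exceedance probabilities are monotone, bounded and MC-consistent", {
  p <- structure(list(loc = 1, scale = 2, shape = 0.1), class = "gev_params")
  lv <- seq(-50, 80, length.out = 200)
  pr <- exceedance_probability(p, lv)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) <= 0))
  expect_equal(exceedance_probability(p, -1e8), 1)

  set.seed(41)
  z <- return_level(p, 50)
  draws <- qgev(runif(1e6), p$loc, p$scale, p$shape)
  emp <- mean(draws > z)
  se <- sqrt(0.02 * 0.98 / 1e6)
  expect_lt(abs(emp - 0.02), 3 * se)
})

test_that("hazard under a warmed state composes the two primitives", {
  set.seed(19)
  present <- lapply(1:6, function(i)
    structure(list(loc = runif(1, 5, 15), scale = runif(1, 0.5, 3),
                   shape = runif(1, 0, 0.4)), class = "gev_params"))
  # identical future -> exactly 1/T
  expect_equal(hazard_under_state(present, present, 500),
               rep(1 / 500, 6))
  # upward location shift -> strictly larger probability
  future <- lapply(present, function(p) {
    p$loc <- p$loc + 1; p
  })
  p_fut <- hazard_under_state(present, future, 500)
  expect_true(all(p_fut > 1 / 500))
  # cell-by-cell manual composition
  manual <- vapply(1:6, function(i)
    exceedance_probability(future[[i]], return_level(present[[i]], 500)),
    numeric(1))
  expect_identical(p_fut, manual)
  # masked cells propagate
  future[2] <- list(NULL); present[2] <- list(NULL)
  expect_true(is.na(hazard_under_state(present, future, 500)[2]))
})

test_that("profile-likelihood intervals behave across alpha and sample size", {
  set.seed(11)
  x300 <- qgev(runif(300), 10, 2, 0.1)
  ci <- suppressWarnings(confidence_interval(x300, 500))
  expect_true(ci$converged)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  # alpha = 1 collapses onto the point estimate
  ci1 <- suppressWarnings(confidence_interval(x300, 500, alpha = 1))
  expect_equal(ci1$lower, ci1$estimate)
  expect_equal(ci1$upper, ci1$estimate)
  # fewer blocks -> wider interval for the same generating process
  ci30 <- suppressWarnings(confidence_interval(x300[1:30], 500))
  expect_gt(ci30$upper - ci30$lower, ci$upper - ci$lower)
})

test_that("profile-likelihood intervals cover the true return level", {
  set.seed(7)
  true_z <- qgev(1 - 1 / 500, 10, 2, 0)
  cover <- vapply(1:200, function(r) {
    x <- qgev(runif(100), 10, 2, 0)
    ci <- suppressWarnings(confidence_interval(x, 500))
    if (!ci$converged) return(NA)
    ci$lower <= true_z && true_z <= ci$upper
  }, logical(1))
  expect_gt(mean(!is.na(cover)), 0.95)       # convergence is the norm
  expect_gte(mean(cover, na.rm = TRUE), 0.90)
  expect_lte(mean(cover, na.rm = TRUE), 1.00)
})

test_that("Anderson-Darling test rejects a clearly non-GEV sample", {
  set.seed(29)
  x <- runif(200)                      # uniform is far from any fitted GEV
  res <- ad_test_gev(x, n_boot = 200)
  expect_lt(res$p_value, 0.05)
  expect_true(is.finite(res$statistic))
})

test_that("duplicating a sample lowers the Anderson-Darling p-value on average", {
  set.seed(37)
  diffs <- vapply(1:15, function(r) {
    x <- qgev(runif(60), 10, 2, 0.1)
    p1 <- ad_test_gev(x, n_boot = 100)$p_value
    p2 <- ad_test_gev(rep(x, 2), n_boot = 100)$p_value
    p1 - p2
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("degenerate series yield a missing AD p-value, not an error", {
  res <- ad_test_gev(rep(0, 40), n_boot = 50)
  expect_true(is.na(res$p_value))
})

test_that("Gumbel fallback is continuous at the constraint boundary", {
  # samples whose L-skewness approaches the Gumbel value from below give
  # fits converging to the Gumbel fit of the same sample
  set.seed(43)
  x <- qgev(runif(5000), 10, 2, 0)
  f <- fit_gev_lmoments(x)
  lm <- sample_lmoments(x)
  gum_scale <- lm$l2 / log(2)
  gum_loc <- lm$l1 - 0.57721566490153286 * gum_scale
  if (f$shape == 0) {
    expect_equal(f$scale, gum_scale)
    expect_equal(f$loc, gum_loc)
  } else {
    expect_lt(abs(f$shape), 0.03)
    expect_equal(f$scale, gum_scale, tolerance = 0.02)
    expect_equal(f$loc, gum_loc, tolerance = 0.02)
  }
})
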
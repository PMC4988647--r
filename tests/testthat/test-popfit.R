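test_that("burst weights are gamma-corrected sizes", {
  d <- std_analyzed()
  bc <- burst_counts(d)
  expect_equal(burst_weights(d),
               pmax(bc$na + bc$nd, 0))
  expect_equal(burst_weights(d, gamma = 0.5, add_naa = TRUE),
               pmax(bc$na + 0.5 * bc$nd +
                      ifelse(is.na(bc$naa), 0, bc$naa), 0))
})

test_that("size weighting reduces the variance of the population E estimate", {
  set.seed(17)
  est <- replicate(200, {
    sizes <- pmax(rgeom(60, 1 / 40), 5)
    e <- rbinom(60, sizes, 0.6) / sizes
    c(weighted = sum(sizes * e) / sum(sizes), plain = mean(e))
  })
  expect_lt(var(est["weighted", ]), var(est["plain", ]))
})

test_that("weighted histogram: mass conservation and bin conventions", {
  h <- weighted_histogram(0.5, weights = 3, binwidth = 0.03)
  expect_equal(sum(h$mass), 3)
  set.seed(2)
  v <- runif(500); w <- rexp(500)
  h2 <- weighted_histogram(v, w, 0.03)
  expect_equal(sum(h2$mass), sum(w))
  # [0, 1] data with binwidth 0.03: 34 half-open bins covering [0, 1.02)
  h3 <- weighted_histogram(c(0, v, 1), binwidth = 0.03)
  expect_length(h3$mass, 34)
  expect_equal(h3$edges[1], 0)
  expect_equal(h3$edges[35], 1.02)
  # half-open bins: a value on an interior edge counts in the upper bin
  h4 <- weighted_histogram(c(0.03, 0.059), binwidth = 0.03)
  expect_equal(h4$mass[1], 2)
  expect_error(weighted_histogram(numeric(0)), "empty")
})

test_that("weighted KDE integrates to one and matches standard KDE", {
  set.seed(6)
  v <- c(rnorm(300, 0.3, 0.05), rnorm(300, 0.7, 0.05))
  k <- weighted_kde(v, bandwidth = 0.03)
  expect_equal(sum(k$y) * diff(k$x[1:2]), 1, tolerance = 1e-3)
  # equal weights reduce to the unweighted estimate
  k2 <- weighted_kde(v, weights = rep(2, length(v)), bandwidth = 0.03)
  expect_equal(k$y, k2$y)
  # cross-check against stats::density with the same Gaussian kernel
  # (density() bins the sample onto an FFT grid, hence the loose tolerance)
  dref <- density(v, bw = 0.03, kernel = "gaussian", n = 512,
                  from = min(k$x), to = max(k$x))
  expect_equal(k$y, dref$y, tolerance = 0.05)
  # both population modes recovered within a bandwidth
  peaks <- k$x[order(k$y, decreasing = TRUE)]
  expect_lt(min(abs(peaks[1] - c(0.3, 0.7))), 0.03)
  # single value: a Gaussian centered there
  k1 <- weighted_kde(0.4, bandwidth = 0.05)
  expect_equal(k1$y, dnorm(k1$x, 0.4, 0.05), tolerance = 1e-9)
})

test_that("two-Gaussian histogram fit recovers centers and uncertainty scale", {
  set.seed(23)
  v <- c(rnorm(1500, 0.3, 0.05), rnorm(1500, 0.7, 0.05))
  f <- fit_histogram(v, model = "gauss2", binwidth = 0.03)
  expect_equal(unname(f$coef["mu1"]), 0.3, tolerance = 0.01)
  expect_equal(unname(f$coef["mu2"]), 0.7, tolerance = 0.01)
  expect_true(all(f$stderr[c("mu1", "mu2")] < 0.01))
  expect_lt(abs(f$redchi - 1), 0.6)
  expect_true(is.finite(f$aic) && is.finite(f$bic))
  # centers come out ordered regardless of the data ordering
  expect_lte(f$coef["mu1"], f$coef["mu2"])
  s <- summary(f)
  expect_s3_class(s, "summary.fret_fit")
  expect_equal(unname(coef(f)["mu1"]), unname(f$coef["mu1"]))
})

test_that("single-Gaussian fit on well-specified data has redchi near 1", {
  set.seed(29)
  redchis <- replicate(20, {
    v <- rnorm(1200, 0.5, 0.06)
    fit_histogram(v, model = "gauss1", binwidth = 0.03)$redchi
  })
  expect_lt(abs(mean(redchis) - 1), 0.3)
})

test_that("BIC prefers two Gaussians on genuinely bimodal data", {
  set.seed(37)
  wins <- replicate(100, {
    v <- c(rnorm(250, 0.3, 0.05), rnorm(250, 0.7, 0.05))
    f1 <- fit_histogram(v, model = "gauss1", binwidth = 0.03)
    f2 <- fit_histogram(v, model = "gauss2", binwidth = 0.03)
    f2$bic < f1$bic
  })
  expect_gte(mean(wins), 0.95)
})

test_that("plateau model reduces to two Gaussians at zero amplitude", {
  spec2 <- phburst:::fit_models("gauss2", c(0.3, 0.7), c(1, 1), 2)
  specp <- phburst:::fit_models("gauss2_plateau", c(0.3, 0.7), c(1, 1), 2)
  p <- list(A1 = 1, mu1 = 0.3, sigma1 = 0.05, A2 = 2, mu2 = 0.7,
            sigma2 = 0.04)
  x <- seq(-0.1, 1.1, 0.01)
  expect_equal(specp$fn(x, c(p, Ab = 0)), spec2$fn(x, p))
  # with amplitude, the plateau adds mass only between/near the centers
  y <- specp$fn(x, c(p, Ab = 1)) - spec2$fn(x, p)
  expect_equal(y[x >= 0.3 & x <= 0.7], rep(1, sum(x >= 0.3 & x <= 0.7)))
  expect_lt(y[x == -0.1], 1e-8)
  # a plateau-bridged sample still fits with sensible centers
  set.seed(3)
  v <- c(rnorm(800, 0.3, 0.05), rnorm(800, 0.7, 0.05), runif(250, 0.3, 0.7))
  fp <- fit_histogram(v, model = "gauss2_plateau", binwidth = 0.03)
  expect_equal(unname(fp$coef["mu1"]), 0.3, tolerance = 0.03)
  expect_equal(unname(fp$coef["mu2"]), 0.7, tolerance = 0.03)
  expect_gt(fp$coef["Ab"], 0)
})

test_that("weighted EM: closed form at k = 1, recovery and monotonicity", {
  set.seed(41)
  v <- rnorm(400, 0.4, 0.1); w <- rexp(400) + 0.1
  f1 <- fit_em_gaussian(v, w, k = 1)
  wm <- sum(w * v) / sum(w)
  ws <- sqrt(sum(w * (v - wm)^2) / sum(w))
  expect_equal(unname(f1$coef["mu1"]), wm, tolerance = 1e-6)
  expect_equal(unname(f1$coef["sigma1"]), ws, tolerance = 1e-6)

  v2 <- c(rnorm(1000, 0.3, 0.05), rnorm(2000, 0.7, 0.05))
  f2 <- fit_em_gaussian(v2, k = 2)
  expect_equal(unname(f2$coef["mu1"]), 0.3, tolerance = 0.01)
  expect_equal(unname(f2$coef["mu2"]), 0.7, tolerance = 0.01)
  expect_equal(unname(f2$coef["fraction1"]), 1 / 3, tolerance = 0.05)
  expect_true(all(diff(f2$loglik_trace) >= -1e-8))
  expect_true(is.finite(f2$aic) && is.finite(f2$bic))
  expect_error(fit_em_gaussian(v2, k = 4), "k must be")
  expect_error(fit_em_gaussian(rnorm(15), k = 2), "need more than")
})

test_that("histogram and EM center estimates agree on mixtures", {
  set.seed(47)
  v <- c(rnorm(1200, 0.25, 0.06), rnorm(1000, 0.75, 0.06))
  fh <- fit_histogram(v, model = "gauss2", binwidth = 0.03)
  fe <- fit_em_gaussian(v, k = 2)
  for (mu in c("mu1", "mu2")) {
    se <- sqrt(fh$stderr[mu]^2 + max(fe$stderr[mu]^2, 1e-6, na.rm = TRUE))
    expect_lt(abs(fh$coef[mu] - fe$coef[mu]), 2 * se)
  }
})
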
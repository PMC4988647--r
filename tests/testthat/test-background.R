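test_that("inter-photon delays: units, telescoping, validation", {
  expect_equal(interphoton_delays(c(0, 10, 30), 1e-3), c(0.010, 0.020))
  expect_equal(interphoton_delays(seq(0, 50, by = 5), 1), rep(5, 10))
  set.seed(1)
  ts <- cumsum(round(rexp(500, 1e-3)))
  dl <- interphoton_delays(ts, 1e-6)
  expect_true(all(dl >= 0))
  expect_equal(sum(dl), (ts[500] - ts[1]) * 1e-6)
  expect_error(interphoton_delays(c(3), 1), "at least 2")
})

test_that("truncated-exponential MLE: closed form and numeric oracle", {
  fit <- bg_fit_mle(c(0.003, 0.004, 0.005), 0.002, min_tail = 1)
  expect_equal(fit$rate, 500)
  expect_equal(fit$n_tail, 3)
  expect_error(bg_fit_mle(rep(0.002, 20), 0.002), "degenerate")
  expect_error(bg_fit_mle(c(0.003, 0.004), 0.002, min_tail = 10),
               "required")

  # MLE equals the numeric maximizer of the truncated-exponential
  # log-likelihood to 1e-6 relative tolerance
  set.seed(42)
  for (i in 1:20) {
    lam <- runif(1, 100, 5000)
    dl <- rexp(2000, lam) + runif(2000, 0, 1e-4)  # arbitrary positive data
    tmin <- quantile(dl, runif(1, 0, 0.5))
    fit <- bg_fit_mle(dl, tmin)
    tail <- dl[dl >= tmin]
    nll <- function(l) -sum(log(l) - l * (tail - tmin))
    opt <- optimize(nll, c(fit$rate / 10, fit$rate * 10), tol = 1e-10)
    expect_equal(fit$rate, opt$minimum, tolerance = 1e-6)
  }

  # Monte-Carlo consistency at lambda = 1000
  set.seed(9)
  expect_equal(bg_fit_mle(rexp(1e5, 1000), 0)$rate, 1000,
               tolerance = 0.01)
})

test_that("MLE bias vanishes with sample size and ignores time offsets", {
  set.seed(21)
  bias <- sapply(c(1e3, 1e4, 1e5), function(n)
    mean(replicate(5, abs(bg_fit_mle(rexp(n, 1000), 0)$rate - 1000))) /
      1000)
  expect_lt(bias[3], 0.005)
  expect_lt(bias[3], bias[1])
  # adding a constant offset to all timestamps leaves delays unchanged
  ts <- cumsum(round(rexp(5000, 0.002)))
  expect_identical(interphoton_delays(ts, 1e-6),
                   interphoton_delays(ts + 1e9, 1e-6))
})

test_that("least-squares tail fit agrees with MLE and handles mixtures", {
  set.seed(33)
  dl <- rexp(5e4, 1000)
  mle <- bg_fit_mle(dl, 0)$rate
  lsq <- bg_fit_lsq(dl, 0)$rate
  expect_equal(lsq, mle, tolerance = 0.05)

  # two-component delays: short-delay excess plus exponential tail;
  # with tail_min above the knee the tail rate is recovered within 5%
  dl2 <- c(rexp(2e4, 5e4), rexp(5e4, 1000))
  expect_equal(bg_fit_lsq(dl2, 5e-4)$rate, 1000, tolerance = 0.05)
  expect_equal(bg_fit_mle(dl2, 5e-4)$rate, 1000, tolerance = 0.05)

  expect_error(bg_fit_lsq(rep(0.001, 50), 0.5e-3), "nonzero")
})

test_that("automatic tail threshold converges and excludes bursts", {
  set.seed(55)
  dl <- rexp(2e4, 1000)
  th <- auto_tail_min(dl)
  expect_equal(attr(th, "fit")$rate, 1000, tolerance = 0.03)
  # fixed point: refitting from the returned threshold moves the rate < 1%
  again <- bg_fit_mle(dl, th)
  expect_lt(abs(again$rate - attr(th, "fit")$rate) /
              attr(th, "fit")$rate, 0.01)

  # mixture: bursts at 50 kcps on top of 1 kcps background
  dl_mix <- c(rexp(3000, 5e4), rexp(2e4, 1000))
  th_mix <- auto_tail_min(dl_mix)
  expect_gt(th_mix, 1 / 5e4)  # threshold sits beyond the burst component
  expect_equal(attr(th_mix, "fit")$rate, 1000, tolerance = 0.10)
  expect_error(auto_tail_min(rexp(50, 1)), "at least 100")
})

test_that("windowed background estimation on constant-rate data", {
  sim <- simulate_fret(sim_config(
    duration_s = 120, alternation = alternation("none"),
    bg_rates = c(Dem = 1200, Aem = 800), burst_rate = 0, seed = 77))
  d <- estimate_background(sim$data, window_s = 30)
  bg <- d$background[[1]]
  expect_equal(bg$n_periods, 4)
  expect_equal(bg$stops[4], acquisition_duration(sim$data$spots[[1]]))
  for (lab in c("all", "Dem", "Aem")) {
    truth <- c(all = 2000, Dem = 1200, Aem = 800)[[lab]]
    se <- bg$rates[[lab]] / sqrt(bg$n_tail[[lab]])
    expect_true(all(abs(bg$rates[[lab]] - truth) < 3 * se))
  }
  # no trend on constant-rate data: slope consistent with 0
  r <- bg$rates$all
  fit <- summary(lm(r ~ seq_along(r)))
  expect_gt(coef(fit)[2, 4], 0.05)
  # sum rule: rate(all) close to sum of component rates
  expect_equal(bg$rates$all, bg$rates$Dem + bg$rates$Aem,
               tolerance = 0.05)

  # window larger than acquisition: exactly one period
  d1 <- estimate_background(sim$data, window_s = 1e4)
  expect_equal(d1$background[[1]]$n_periods, 1)
})

test_that("partial final windows merge below half width", {
  e <- phburst:::bg_period_edges(100, 30)   # 10 s remainder < 15 s
  expect_equal(length(e$starts), 3)
  expect_equal(e$stops, c(30, 60, 100))
  e2 <- phburst:::bg_period_edges(110, 30)  # 20 s remainder >= 15 s
  expect_equal(length(e2$starts), 4)
  expect_equal(e2$stops, c(30, 60, 90, 110))
})

test_that("rate lookup by time, edge convention, composite streams", {
  sim <- simulate_fret(sim_config(
    duration_s = 90, alternation = alternation("none"),
    bg_rates = c(Dem = 1500, Aem = 1000), burst_rate = 0, seed = 8))
  d <- estimate_background(sim$data, window_s = 30, streams = list(
    ph_sel(dex = "Dem"), ph_sel(dex = "Aem")))
  bg <- d$background[[1]]
  expect_equal(bg_rate_at(bg, ph_sel(dex = "Dem"), 75),
               bg$rates$Dem[3])
  # a boundary time belongs to the later window
  expect_equal(bg_rate_at(bg, ph_sel(dex = "Dem"), 30),
               bg$rates$Dem[2])
  # composite stream falls back to the sum of components
  expect_equal(bg_rate_at(bg, ph_sel(all = TRUE), 10),
               bg$rates$Dem[1] + bg$rates$Aem[1])
})

test_that("sparse windows inherit a neighbor estimate with a warning", {
  # 10 s of photons, then 50 s of silence: second window nearly empty
  set.seed(4)
  ticks <- sort(c(round(runif(3000, 0, 1e7)), 6e7))
  d <- fret_data(toy_spot(ticks, rep(c("Dem", "Aem"), length.out = 3001),
                          unit = 1e-6))
  ws <- capture_warnings(db <- estimate_background(d, window_s = 30,
                                                   tail_min = 1e-4))
  expect_match(ws, "neighboring window", all = TRUE)
  expect_gt(length(ws), 0)
  bg <- db$background[[1]]
  expect_false(anyNA(bg$rates$all))
  expect_equal(bg$rates$all[2], bg$rates$all[1])
})

test_that("per-stream tail thresholds are honored", {
  sim <- simulate_fret(sim_config(
    duration_s = 30, alternation = alternation("none"),
    bg_rates = c(Dem = 1500, Aem = 1000), burst_rate = 0, seed = 13))
  d <- estimate_background(sim$data, window_s = 30,
                           tail_min = list(all = 1e-4, Dem = 2e-4,
                                           Aem = "auto"))
  bg <- d$background[[1]]
  expect_equal(bg$thresholds$all, 1e-4)
  expect_equal(bg$thresholds$Dem, 2e-4)
  expect_true(bg$thresholds$Aem > 0)
  expect_equal(bg$rates$Dem, 1500, tolerance = 0.1)
  expect_error(estimate_background(sim$data, tail_min = list(all = 1e-4)),
               "missing")
})
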
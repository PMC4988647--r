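fake_bg <- function(rates, alternated = FALSE) {
  structure(list(window_s = 10, n_periods = 1, starts = 0, stops = 10,
                 rates = as.list(rates),
                 thresholds = lapply(rates, function(x) 1e-3),
                 n_tail = lapply(rates, function(x) 100),
                 method = "mle", alternated = alternated),
            class = "bg_estimate")
}

fake_bursts <- function(nd_raw, na_raw, width, naa_raw = NA_real_) {
  n <- length(nd_raw)
  structure(data.frame(istart = 1, istop = nd_raw + na_raw,
                       start_tick = 0, stop_tick = width / 1e-6,
                       t_start = 0, t_stop = width, width = width,
                       n_all = nd_raw + na_raw, nd_raw = nd_raw,
                       na_raw = na_raw, naa_raw = naa_raw,
                       nda_raw = NA_real_),
            params = list(m = 10), reference = ph_sel(all = TRUE),
            spot = 1, class = c("burst_set", "data.frame"))
}

test_that("background correction subtracts rate x width per stream", {
  bg <- fake_bg(c(all = 1500, Dem = 1000, Aem = 500))
  b <- fake_bursts(nd_raw = c(40, 10), na_raw = c(20, 5),
                   width = c(2e-3, 0))
  out <- background_correct(b, bg)
  expect_equal(out$nd, c(38, 10))     # 40 - 1000 * 2 ms
  expect_equal(out$na, c(19, 5))      # zero width: no subtraction
  expect_true(all(is.na(out$naa)))
})

test_that("mean subtracted background matches rate x width on simulation", {
  d <- std_analyzed()
  bs <- d$bursts[[1]]
  bc <- background_correct(bs, d$background[[1]])
  subtracted <- bs$nd_raw - bc$nd
  expect_equal(mean(subtracted),
               700 * mean(bs$width), tolerance = 0.15)
})

test_that("leakage and direct-excitation corrections on na", {
  expect_equal(leakage_direx_correct(10, 5, 8, 0.15, 0.08), 2.86)
  expect_equal(leakage_direx_correct(10, 5, 8, 0, 0), 5)
  expect_equal(leakage_direx_correct(c(1, 2), c(3, 4), c(0, 0), 0.1, 0.5),
               c(2.9, 3.8))
})

test_that("gamma-corrected burst sizes follow the two size formulas", {
  expect_equal(burst_size(10, 5, gamma = 0.5), 10)
  expect_equal(burst_size(10, 5, 8, gamma = 1, add_naa = TRUE), 23)
  expect_equal(burst_size(10, 5, gamma = 1), 15)
  # linearity and monotonicity in gamma
  expect_equal(burst_size(20, 10, gamma = 0.7), 2 * burst_size(10, 5, gamma = 0.7))
  expect_lt(burst_size(10, 5, gamma = 0.5), burst_size(10, 5, gamma = 1.5))
})

test_that("proximity ratio and stoichiometry limits", {
  expect_equal(proximity_ratio(3, 1), 0.25)
  expect_equal(proximity_ratio(7, 0), 0)
  expect_true(is.na(proximity_ratio(0, 0)))
  expect_equal(stoichiometry(10, 5, 0), 1)    # D-only limit
  expect_equal(stoichiometry(0, 0, 12), 0)    # A-only limit
  expect_true(is.na(stoichiometry(0, 0, 0)))
  # binomial sampling: mean E_pr near the partition probability
  set.seed(88)
  na <- rbinom(2000, 50, 0.6)
  e <- proximity_ratio(50 - na, na)
  expect_lt(abs(mean(e) - 0.6), 3 * sd(e) / sqrt(2000))
})

test_that("population-level E correction: limits and inversion", {
  expect_equal(correct_E_population(0.5, 1, 0, 0), 0.5)
  expect_equal(correct_E_population(0.5, 2, 0, 0), 1 / 3)
  expect_equal(correct_E_population(0.3, 0.75, 0, 0),
               0.3 / (0.3 * 0.25 + 0.75))
  # forward (E -> E_pr under the counts model) then inverse is identity
  grid <- expand.grid(E = seq(0.05, 0.95, 0.15),
                      g = c(0.4, 0.85, 1, 1.6),
                      lk = c(0, 0.15, 0.3), dirt = c(0, 0.08, 0.2))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      nd <- 100 * (1 - E) / g
      na_obs <- 100 * E + lk * nd + dirt * 100
      E_pr <- na_obs / (na_obs + nd)
      expect_equal(correct_E_population(E_pr, g, lk, dirt), E,
                   tolerance = 1e-12)
    })
  }
})

test_that("counts-level and population-level corrections agree", {
  set.seed(12)
  for (i in 1:300) {
    nd <- runif(1, 1, 100); na <- runif(1, 1, 100)
    naa <- runif(1, 1, 100)
    g <- runif(1, 0.3, 2.5); lk <- runif(1, 0, 0.3)
    dir <- runif(1, 0, 0.2)
    na_c <- leakage_direx_correct(nd, na, naa, lk, dir)
    E_counts <- na_c / (na_c + g * nd)
    S_counts <- (na_c + g * nd) / (na_c + g * nd + naa)
    E_pr <- proximity_ratio(nd, na)
    S_raw <- stoichiometry(nd, na, naa, 1)
    dirt <- dir_ex_total_coeff(nd, na, naa, g, lk, dir)
    expect_equal(correct_E_population(E_pr, g, lk, dirt), E_counts,
                 tolerance = 1e-9)
    expect_equal(correct_S_population(E_pr, S_raw, g, lk, dir), S_counts,
                 tolerance = 1e-9)
  }
  # identity at default coefficients, A-only S = 0 under any coefficients
  expect_equal(correct_S_population(0.4, 0.7, 1, 0, 0), 0.7)
  expect_equal(correct_S_population(NA_real_, 0, 0.7, 0.2, 0.1), 0)
})

test_that("leakage round trip on donor-only simulation recovers E = 0", {
  sim <- simulate_fret(sim_config(
    duration_s = 60,
    populations = data.frame(fraction = 1, E = 0, S = 0.5, rate = 1e5,
                             transit = 1e-3),
    leakage = 0.15, seed = 99))
  d <- apply_alternation(sim$data)
  d <- estimate_background(d, window_s = 30)
  d <- burst_search(d, m = 10, F = 6)
  d <- set_corrections(d, leakage = 0.15)
  d <- select_bursts(d, "size", th1 = 30)
  bc <- burst_counts(d)
  E_corr <- bc$na / (bc$na + bc$nd)
  expect_lt(abs(mean(E_corr, na.rm = TRUE)), 0.03)
  # without the correction the same bursts sit near the leakage fraction
  expect_gt(mean(bc$E_pr, na.rm = TRUE), 0.10)
})

test_that("burst_counts assembles corrected quantities coherently", {
  d <- std_analyzed()
  d <- set_corrections(d, gamma = 0.8, leakage = 0.1, dir_ex = 0.05)
  bc <- burst_counts(d)
  expect_equal(bc$size_dex, bc$na + 0.8 * bc$nd)
  expect_equal(bc$size_all, bc$size_dex + ifelse(is.na(bc$naa), 0, bc$naa))
  # E_pr is computed before leakage/dir corrections are applied to na
  na_bg <- bc$na + 0.1 * bc$nd + 0.05 * bc$naa
  expect_equal(bc$E_pr, na_bg / (na_bg + bc$nd))
  tab <- corrected_burst_table(d)
  expect_true(all(c("E_corr", "S_corr", "size_all") %in% names(tab)))
  expect_equal(nrow(tab), nrow(bc))
})
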
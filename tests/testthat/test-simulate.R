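test_that("identical seeds reproduce the simulation bit for bit", {
  cfg <- sim_config(duration_s = 10, seed = 123)
  s1 <- simulate_fret(cfg)
  s2 <- simulate_fret(cfg)
  expect_identical(s1$data$spots[[1]]$timestamps,
                   s2$data$spots[[1]]$timestamps)
  expect_identical(s1$data$spots[[1]]$detectors,
                   s2$data$spots[[1]]$detectors)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_fret(sim_config(duration_s = 10, seed = 124))
  expect_false(identical(s1$data$spots[[1]]$timestamps,
                         s3$data$spots[[1]]$timestamps))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(populations = data.frame(
    fraction = c(0.5, 0.4), E = 0.5, S = 0.5, rate = 1e5,
    transit = 1e-3)), "sum to 1")
  expect_error(sim_config(populations = data.frame(
    fraction = 1, E = 1.2, S = 0.5, rate = 1e5, transit = 1e-3)),
    "E must be")
  expect_error(sim_config(duration_s = -1), "positive")
  expect_error(sim_config(bg_rates = c(DexDem = 100)), "named")
  expect_error(sim_config(dynamics = list(E_states = 0.5, k_ab = 1,
                                          k_ba = 1)), "dynamics")
  expect_error(simulate_two_state(sim_config()), "dynamics")
})

test_that("background-only stream delays are exponential", {
  sim <- simulate_fret(sim_config(
    duration_s = 30, alternation = alternation("none"),
    bg_rates = c(Dem = 1200, Aem = 800), burst_rate = 0, seed = 201))
  sp <- sim$data$spots[[1]]
  expect_equal(nrow(sim$truth), 0)
  for (spec in list(list(ph_sel(dex = "Dem"), 1200),
                    list(ph_sel(dex = "Aem"), 800),
                    list(ph_sel(all = TRUE), 2000))) {
    dl <- interphoton_delays(stream_timestamps(sp, spec[[1]]),
                             sp$timestamps_unit)
    ks <- suppressWarnings(ks.test(dl, "pexp", spec[[2]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("total counts over windows are Poisson-dispersed", {
  sim <- simulate_fret(sim_config(
    duration_s = 60, alternation = alternation("none"),
    bg_rates = c(Dem = 1000, Aem = 1000), burst_rate = 0, seed = 203))
  t_s <- sim$data$spots[[1]]$timestamps * sim$data$spots[[1]]$timestamps_unit
  counts <- tabulate(findInterval(t_s, seq(0, 60, by = 2)), nbins = 30)
  # index-of-dispersion test: (n-1) s^2 / mean ~ chi-square(n-1)
  disp <- (30 - 1) * var(counts) / mean(counts)
  expect_gt(disp, qchisq(0.005, 29))
  expect_lt(disp, qchisq(0.995, 29))
})

test_that("bursts create a short-delay excess over the exponential tail", {
  sim <- simulate_fret(sim_config(duration_s = 30, seed = 205))
  sp <- sim$data$spots[[1]]
  dl <- interphoton_delays(sp$timestamps, sp$timestamps_unit)
  # rate of the exponential tail (background), from the auto threshold
  lam <- attr(auto_tail_min(dl), "fit")$rate
  q <- 5e-6
  observed <- mean(dl < q)
  tail_pred <- 1 - exp(-lam * q)
  expect_gt(observed, 2 * tail_pred)
  # without bursts the same fraction matches the exponential prediction
  sim0 <- simulate_fret(sim_config(duration_s = 30, burst_rate = 0,
                                   seed = 205))
  dl0 <- interphoton_delays(sim0$data$spots[[1]]$timestamps,
                            sp$timestamps_unit)
  lam0 <- attr(auto_tail_min(dl0), "fit")$rate
  expect_equal(mean(dl0 < q), 1 - exp(-lam0 * q), tolerance = 0.1)
})

test_that("simulated streams hit their configured rates and E", {
  sim <- simulate_fret(sim_config(duration_s = 60, burst_rate = 0,
                                  seed = 207))
  d <- apply_alternation(sim$data)
  sp <- d$spots[[1]]
  T_s <- acquisition_duration(sp)
  for (nm in c("DexDem", "DexAem", "AexAem", "AexDem")) {
    n <- sum(stream_mask(sp, canonical_streams(TRUE)[[nm]]))
    truth <- c(DexDem = 700, DexAem = 450, AexAem = 700,
               AexDem = 150)[[nm]]
    expect_lt(abs(n / T_s - truth), 4 * sqrt(truth * T_s) / T_s)
  }
  # burst photons partition binomially at the population E
  sim2 <- simulate_fret(sim_config(
    duration_s = 60,
    populations = data.frame(fraction = 1, E = 0.75, S = 0.5, rate = 1e5,
                             transit = 1e-3),
    bg_rates = c(DexDem = 1, DexAem = 1, AexAem = 1, AexDem = 1),
    bg_outside_cps = 1, seed = 209))
  d2 <- apply_alternation(sim2$data)
  sp2 <- d2$spots[[1]]
  nd <- sum(stream_mask(sp2, ph_sel(dex = "Dem")))
  na <- sum(stream_mask(sp2, ph_sel(dex = "Aem")))
  expect_equal(na / (na + nd), 0.75, tolerance = 0.02)
  # stoichiometry thinning: naa/ndex tracks (1 - S)/S
  sim3 <- simulate_fret(sim_config(
    duration_s = 60,
    populations = data.frame(fraction = 1, E = 0.5, S = 0.7, rate = 1e5,
                             transit = 1e-3),
    bg_rates = c(DexDem = 1, DexAem = 1, AexAem = 1, AexDem = 1),
    bg_outside_cps = 1, seed = 211))
  sp3 <- apply_alternation(sim3$data)$spots[[1]]
  ndex <- sum(stream_mask(sp3, ph_sel(dex = c("Dem", "Aem"))))
  naa <- sum(stream_mask(sp3, ph_sel(aex = "Aem")))
  expect_equal(naa / ndex, (1 - 0.7) / 0.7, tolerance = 0.05)
})

test_that("two-state limits: frozen and fast-exchange", {
  base <- function(k, seed) sim_config(
    duration_s = 40,
    populations = data.frame(fraction = 1, E = 0.5, S = 0.5, rate = 1e5,
                             transit = 2e-3),
    dynamics = list(E_states = c(0.2, 0.8), k_ab = k, k_ba = k),
    seed = seed)
  analyze <- function(sim) {
    d <- apply_alternation(sim$data)
    d <- estimate_background(d, window_s = 40)
    d <- burst_search(d, m = 10, F = 6)
    d <- select_bursts(d, "size", th1 = 60)
    burst_counts(d)$E_pr
  }
  # k -> 0: each burst frozen in one state; per-burst E bimodal at 0.2/0.8
  e_slow <- analyze(simulate_two_state(base(0.1, 301)))
  expect_gt(mean(abs(e_slow - 0.5) > 0.15), 0.8)
  # k >> photon rate: every burst averages to the stationary mean 0.5
  e_fast <- analyze(simulate_two_state(base(1e6, 303)))
  expect_lt(mean(abs(e_fast - 0.5) > 0.15), 0.2)
  expect_equal(mean(e_fast), 0.5, tolerance = 0.03)
})

test_that("simulation writes a loadable file with ground-truth sidecar", {
  sim <- simulate_fret(sim_config(duration_s = 5, seed = 99))
  f <- withr::local_tempfile(fileext = ".h5")
  write_simulation(sim, f)
  expect_true(file.exists(paste0(f, "_truth.csv")))
  d <- read_photon_hdf5(f)
  expect_identical(d$spots[[1]]$timestamps, sim$data$spots[[1]]$timestamps)
  tr <- read.csv(paste0(f, "_truth.csv"))
  expect_equal(nrow(tr), nrow(sim$truth))
})
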
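#' Simulation configuration
#'
#' Describes a synthetic freely-diffusing smFRET measurement: Poisson
#' background streams, Poisson burst arrivals with exponential transit
#' durations and a constant within-burst photon rate (rectangular transit
#' profile), binomial donor/acceptor partitioning of donor-excitation
#' photons with success probability the population proximity ratio, and a
#' us-ALEX period structure. Defaults describe a typical 300 s single-spot
#' us-ALEX measurement with 2 kcps total in-period background and bursts
#' at 50x the background rate.
#'
#' @param duration_s Acquisition duration, seconds (default 300).
#' @param timestamps_unit Seconds per clock tick (default 12.5 ns).
#' @param alternation An [alternation()] spec; default us-ALEX with a
#'   4000-tick period, `D_ON = c(2100, 3900)`, `A_ON = c(100, 1900)`.
#'   Use `alternation("none")` for single-laser simulations.
#' @param bg_rates Named background rates (counts/s) per canonical stream:
#'   `DexDem`, `DexAem`, `AexAem`, `AexDem` for ALEX (default
#'   700/450/700/150, totalling 2000) or `Dem`, `Aem` otherwise (default
#'   1200/800).
#' @param bg_outside_cps Background photons falling outside both
#'   excitation periods (removed by [apply_alternation()]); ALEX only.
#'   Default 200.
#' @param populations Data frame with one row per molecular species:
#'   `fraction` (summing to 1), `E` (proximity ratio in `[0, 1]`), `S`
#'   (stoichiometry in `(0, 1]`), `rate` (within-burst photon rate,
#'   counts/s, default 1e5) and `transit` (mean transit duration,
#'   seconds, default 1 ms).
#' @param dynamics Optional two-state interconversion:
#'   `list(E_states = c(Ea, Eb), k_ab, k_ba)` with rates in 1/s. When set,
#'   each burst's emitting state follows a continuous-time Markov chain
#'   and each photon is partitioned using the current state's E.
#' @param burst_rate Burst arrival rate, bursts/s (default 1).
#' @param leakage Donor-to-acceptor crosstalk coefficient: leaked
#'   acceptor-channel counts per detected donor-channel count, matching
#'   the convention of [set_corrections()] (default 0).
#' @param dir_ex_prob Per-photon probability that a donor-excitation
#'   photon comes from direct acceptor excitation (registered `Aem`;
#'   default 0).
#' @param seed Integer RNG seed; the simulation is fully reproducible.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(duration_s = 300, timestamps_unit = 12.5e-9,
                       alternation = phburst::alternation(
                         "us_alex", period = 4000, D_ON = c(2100, 3900),
                         A_ON = c(100, 1900)),
                       bg_rates = NULL, bg_outside_cps = 200,
                       populations = data.frame(fraction = 1, E = 0.5,
                                                S = 0.5, rate = 1e5,
                                                transit = 1e-3),
                       dynamics = NULL, burst_rate = 1, leakage = 0,
                       dir_ex_prob = 0, seed = 1) {
  stopifnot(inherits(alternation, "alt_spec"))
  alex <- alternation$mode != "none"
  if (alternation$mode == "ns_alex")
    stop("the simulator supports us-ALEX and single-laser modes")
  if (is.null(bg_rates)) {
    bg_rates <- if (alex) c(DexDem = 700, DexAem = 450, AexAem = 700,
                            AexDem = 150)
                else c(Dem = 1200, Aem = 800)
  }
  need <- if (alex) c("DexDem", "DexAem", "AexAem", "AexDem")
          else c("Dem", "Aem")
  if (!all(need %in% names(bg_rates)))
    stop("bg_rates must be named with: ", paste(need, collapse = ", "))
  if (duration_s <= 0 || timestamps_unit <= 0 || burst_rate < 0 ||
      any(bg_rates < 0))
    stop("durations and rates must be positive")
  if (!is.data.frame(populations) ||
      abs(sum(populations$fraction) - 1) > 1e-9)
    stop("population fractions must sum to 1")
  if (any(populations$E < 0 | populations$E > 1))
    stop("population E must be in [0, 1]")
  if (any(populations$S <= 0 | populations$S > 1))
    stop("population S must be in (0, 1]")
  if (any(populations$rate <= 0 | populations$transit <= 0))
    stop("population rate and transit must be > 0")
  if (!is.null(dynamics)) {
    if (!all(c("E_states", "k_ab", "k_ba") %in% names(dynamics)) ||
        length(dynamics$E_states) != 2 || dynamics$k_ab <= 0 ||
        dynamics$k_ba <= 0)
      stop("dynamics needs E_states (length 2), k_ab > 0, k_ba > 0")
  }
  if (leakage < 0 || leakage >= 1 || dir_ex_prob < 0 || dir_ex_prob >= 1)
    stop("leakage and dir_ex_prob must be in [0, 1)")
  structure(list(duration_s = duration_s,
                 timestamps_unit = timestamps_unit,
                 alternation = alternation, bg_rates = bg_rates,
                 bg_outside_cps = if (alex) bg_outside_cps else 0,
                 populations = populations, dynamics = dynamics,
                 burst_rate = burst_rate, leakage = leakage,
                 dir_ex_prob = dir_ex_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# uniform ticks within one phase range of a repeating period
sim_phase_ticks <- function(n, range, period, n_periods) {
  if (n == 0) return(numeric(0))
  idx <- floor(stats::runif(n) * n_periods)
  phase <- range[1] + floor(stats::runif(n) * (range[2] - range[1]))
  idx * period + phase
}

# two-state CTMC state at given (sorted) times within [t0, t1]
sim_ctmc_states <- function(times, t0, k_ab, k_ba) {
  rates <- c(k_ab, k_ba)
  state <- if (stats::runif(1) < k_ba / (k_ab + k_ba)) 1L else 2L
  out <- integer(length(times))
  t_cur <- t0
  next_jump <- t_cur + stats::rexp(1, rates[state])
  for (i in seq_along(times)) {
    while (next_jump < times[i]) {
      t_cur <- next_jump
      state <- 3L - state
      next_jump <- t_cur + stats::rexp(1, rates[state])
    }
    out[i] <- state
  }
  out
}

#' Simulate a freely-diffusing smFRET measurement
#'
#' Generates a photon record according to a [sim_config()]: independent
#' homogeneous Poisson background processes per photon stream, Poisson
#' burst arrivals, each burst a photon cluster with constant rate over an
#' exponential transit duration, donor/acceptor partitioning binomial in
#' the population (or instantaneous two-state) proximity ratio, optional
#' per-photon leakage and direct-excitation misassignment, and
#' acceptor-excitation counts thinned to match the population
#' stoichiometry. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `"fret_sim"` with elements `data` (a
#'   [fret_data()] measurement, alternation not applied), `truth` (data
#'   frame of injected bursts: `burst`, `t_start`, `t_stop`, `population`,
#'   `E`, `S`, `n_photons` retained) and `config`.
#' @export
simulate_fret <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)
  u <- config$timestamps_unit
  T_s <- config$duration_s
  dur_ticks <- floor(T_s / u)
  alt <- config$alternation
  alex <- alt$mode != "none"
  ticks <- numeric(0); det <- character(0)
  add <- function(tk, dt) {
    ticks <<- c(ticks, tk); det <<- c(det, dt)
  }
  # --- background ---
  if (alex) {
    P <- alt$period
    n_per <- floor(dur_ticks / P)
    cells <- list(DexDem = list(alt$D_ON, "Dem"),
                  DexAem = list(alt$D_ON, "Aem"),
                  AexAem = list(alt$A_ON, "Aem"),
                  AexDem = list(alt$A_ON, "Dem"))
    for (nm in names(cells)) {
      n <- stats::rpois(1, config$bg_rates[[nm]] * T_s)
      add(sim_phase_ticks(n, cells[[nm]][[1]], P, n_per),
          rep(cells[[nm]][[2]], n))
    }
    if (config$bg_outside_cps > 0) {
      # complement of D_ON and A_ON within the period
      on <- rbind(alt$D_ON, alt$A_ON)
      on <- on[order(on[, 1]), , drop = FALSE]
      gaps <- rbind(c(0, on[1, 1]), c(on[1, 2], on[2, 1]),
                    c(on[2, 2], P))
      gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
      glen <- gaps[, 2] - gaps[, 1]
      n <- stats::rpois(1, config$bg_outside_cps * T_s)
      gi <- sample.int(nrow(gaps), n, replace = TRUE, prob = glen)
      add(sim_phase_ticks(n, c(0, 1), P, n_per) %/% P * P +
            gaps[gi, 1] + floor(stats::runif(n) * glen[gi]),
          sample(c("Dem", "Aem"), n, replace = TRUE))
    }
  } else {
    for (nm in names(config$bg_rates)) {
      n <- stats::rpois(1, config$bg_rates[[nm]] * T_s)
      add(floor(stats::runif(n) * dur_ticks), rep(nm, n))
    }
  }
  # --- bursts ---
  n_bursts <- stats::rpois(1, config$burst_rate * T_s)
  pops <- config$populations
  truth <- NULL
  if (n_bursts > 0) {
    t0 <- sort(stats::runif(n_bursts) * T_s)
    pop_id <- sample.int(nrow(pops), n_bursts, replace = TRUE,
                         prob = pops$fraction)
    dur <- stats::rexp(n_bursts, 1 / pops$transit[pop_id])
    n_kept <- integer(n_bursts)
    for (b in seq_len(n_bursts)) {
      p <- pop_id[b]
      n_ph <- stats::rpois(1, pops$rate[p] * dur[b])
      if (n_ph == 0) { n_kept[b] <- 0L; next }
      t_ph <- sort(t0[b] + stats::runif(n_ph) * dur[b])
      tk <- floor(t_ph / u)
      if (alex) {
        phase <- tk %% alt$period
        in_d <- phase >= alt$D_ON[1] & phase < alt$D_ON[2]
        in_a <- phase >= alt$A_ON[1] & phase < alt$A_ON[2]
        wD <- diff(alt$D_ON); wA <- diff(alt$A_ON)
        q <- (wD / wA) * (1 - pops$S[p]) / pops$S[p]
        pD <- min(1, 1 / q); pA <- min(1, q)
        keep <- (in_d & stats::runif(n_ph) < pD) |
                (in_a & stats::runif(n_ph) < pA)
        tk <- tk[keep]; t_ph <- t_ph[keep]
        is_dex <- in_d[keep]
      } else {
        is_dex <- rep(TRUE, length(tk))
      }
      n_i <- length(tk)
      if (n_i == 0) { n_kept[b] <- 0L; next }
      e_ph <- if (!is.null(config$dynamics)) {
        st <- sim_ctmc_states(t_ph, t0[b], config$dynamics$k_ab,
                              config$dynamics$k_ba)
        config$dynamics$E_states[st]
      } else rep(pops$E[p], n_i)
      d_i <- character(n_i)
      dex_idx <- which(is_dex)
      if (length(dex_idx) > 0) {
        r1 <- stats::runif(length(dex_idx))
        is_dir <- r1 < config$dir_ex_prob
        is_acc <- stats::runif(length(dex_idx)) < e_ph[dex_idx]
        # crosstalk convention: leaked acceptor counts per detected donor
        # count equal the leakage coefficient, so the per-photon
        # misassignment probability is leakage / (1 + leakage)
        p_leak <- config$leakage / (1 + config$leakage)
        is_leak <- stats::runif(length(dex_idx)) < p_leak
        d_i[dex_idx] <- ifelse(is_dir | is_acc | (!is_acc & is_leak),
                               "Aem", "Dem")
      }
      d_i[!is_dex] <- "Aem"  # acceptor-excitation signal photons
      add(tk, d_i)
      n_kept[b] <- n_i
    }
    truth <- data.frame(burst = seq_len(n_bursts), t_start = t0,
                        t_stop = t0 + dur, population = pop_id,
                        E = pops$E[pop_id], S = pops$S[pop_id],
                        n_photons = n_kept)
  } else {
    truth <- data.frame(burst = integer(0), t_start = numeric(0),
                        t_stop = numeric(0), population = integer(0),
                        E = numeric(0), S = numeric(0),
                        n_photons = integer(0))
  }
  o <- order(ticks)
  spot <- photon_data(ticks[o], det[o], u, alternation = alt)
  structure(list(data = fret_data(spot,
                                  metadata = list(simulated = TRUE,
                                                  seed = config$seed)),
                 truth = truth, config = config),
            class = "fret_sim")
}

#' Simulate a two-state interconverting measurement
#'
#' Convenience wrapper around [simulate_fret()] requiring the `dynamics`
#' field of the configuration to be set.
#'
#' @param config A [sim_config()] with `dynamics`.
#' @return As [simulate_fret()].
#' @export
simulate_two_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$dynamics))
    stop("config$dynamics must be set for a two-state simulation")
  simulate_fret(config)
}

#' @export
print.fret_sim <- function(x, ...) {
  cat(sprintf("<fret_sim> %.0f s, %d photons, %d injected bursts, seed %d\n",
              x$config$duration_s,
              length(x$data$spots[[1]]$timestamps), nrow(x$truth),
              x$config$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes the photon record as a Photon-HDF5-style file plus a CSV ground
#' truth sidecar.
#'
#' @param sim A `"fret_sim"`.
#' @param path Output HDF5 path; the sidecar is `<path>_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "fret_sim"))
  write_photon_hdf5(sim$data, path)
  utils::write.csv(sim$truth, paste0(path, "_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}
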
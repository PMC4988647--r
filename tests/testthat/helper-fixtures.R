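# Shared fixtures and independent oracles, built in code at test time.

# Brute-force sliding-window oracle: enumerate every m-photon window,
# keep the valid ones, and union overlapping index intervals.
brute_force_search <- function(ts, m, thr_fn) {
  n <- length(ts)
  iv <- NULL
  if (n >= m) {
    for (i in 1:(n - m + 1)) {
      if (ts[i + m - 1] - ts[i] <= m / thr_fn(ts[i]))
        iv <- rbind(iv, c(i, i + m - 1))
    }
  }
  if (is.null(iv)) return(data.frame(istart = integer(0), istop = integer(0)))
  out <- NULL
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (r in 2:nrow(iv)) {
      if (iv[r, 1] <= cur[2]) cur[2] <- max(cur[2], iv[r, 2])
      else { out <- rbind(out, cur); cur <- iv[r, ] }
    }
  }
  out <- rbind(out, cur)
  data.frame(istart = as.integer(out[, 1]), istop = as.integer(out[, 2]))
}

# Data-frame content of a burst set, stripped of search metadata, for
# content-equality comparisons.
plain_df <- function(b) {
  d <- as.data.frame(b)
  attributes(d) <- attributes(d)[c("names", "row.names")]
  as.data.frame(d)
}

# Small deterministic non-ALEX photon_data from explicit ticks/detectors.
toy_spot <- function(ticks, det = rep("Dem", length(ticks)), unit = 1e-3) {
  photon_data(ticks, det, unit)
}

# Default ALEX us-ALEX spec used across tests (period 4000 ticks).
toy_alex <- function() {
  alternation("us_alex", period = 4000, D_ON = c(2100, 3900),
              A_ON = c(100, 1900))
}

# A cached standard ALEX simulation shared by several test files.
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_fret(sim_config(duration_s = 60, seed = 20))
    cache
  }
})

# The same measurement analyzed through background + burst search.
std_analyzed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- apply_alternation(std_sim()$data)
      d <- estimate_background(d, window_s = 30)
      cache <<- burst_search(d, m = 10, F = 6)
    }
    cache
  }
})
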
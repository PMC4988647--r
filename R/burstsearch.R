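#' Sliding-window burst search (low level)
#'
#' Finds bursts as regions where the local photon rate, computed over `m`
#' consecutive photons, exceeds a (possibly time-dependent) threshold rate.
#' Index `i` starts a valid window iff
#' `ts[i + m - 1] - ts[i] <= m / threshold_rate(ts[i])` (the threshold is
#' evaluated at the window's first photon; the comparison is inclusive).
#' Overlapping valid windows (start indices closer than `m`) merge into a
#' single burst spanning from the first valid start to the last valid
#' start plus `m - 1`; by construction every burst contains at least `m`
#' photons.
#'
#' @param ts Sorted photon times in seconds.
#' @param m Photons per window (`>= 2`).
#' @param threshold_rate_fn Function mapping a vector of times (seconds) to
#'   threshold rates (counts/s).
#' @return A data frame with 1-based inclusive columns `istart`, `istop`;
#'   zero rows when fewer than `m` photons or no valid window.
#' @export
sliding_window_search <- function(ts, m, threshold_rate_fn) {
  stopifnot(m >= 2)
  n <- length(ts)
  empty <- data.frame(istart = integer(0), istop = integer(0))
  if (n < m) return(empty)
  starts_t <- ts[seq_len(n - m + 1)]
  dt <- ts[m:n] - starts_t
  valid <- which(dt <= m / threshold_rate_fn(starts_t))
  if (length(valid) == 0) return(empty)
  brk <- which(diff(valid) > m - 1)
  first <- valid[c(1, brk + 1)]
  last <- valid[c(brk, length(valid))]
  data.frame(istart = as.integer(first), istop = as.integer(last + m - 1))
}

count_in_intervals <- function(stream_ticks, start_tick, stop_tick) {
  # photons with start_tick <= t <= stop_tick (ticks are integral)
  findInterval(stop_tick, stream_ticks) -
    findInterval(start_tick - 0.5, stream_ticks)
}

burst_raw_counts <- function(spot, start_tick, stop_tick, alternated) {
  streams <- canonical_streams(alternated)
  cnt <- lapply(streams, function(s)
    count_in_intervals(stream_timestamps(spot, s), start_tick, stop_tick))
  if (alternated) {
    data.frame(n_all = cnt$all, nd_raw = cnt$DexDem, na_raw = cnt$DexAem,
               naa_raw = cnt$AexAem, nda_raw = cnt$AexDem)
  } else {
    data.frame(n_all = cnt$all, nd_raw = cnt$Dem, na_raw = cnt$Aem,
               naa_raw = NA_real_, nda_raw = NA_real_)
  }
}

make_burst_set <- function(spot, iv, ref_ticks, sel, params, spot_index,
                           alternated) {
  if (nrow(iv) == 0) {
    bs <- data.frame(istart = integer(0), istop = integer(0),
                     start_tick = numeric(0), stop_tick = numeric(0),
                     t_start = numeric(0), t_stop = numeric(0),
                     width = numeric(0), n_all = numeric(0),
                     nd_raw = numeric(0), na_raw = numeric(0),
                     naa_raw = numeric(0), nda_raw = numeric(0))
  } else {
    start_tick <- ref_ticks[iv$istart]
    stop_tick <- ref_ticks[iv$istop]
    unit <- spot$timestamps_unit
    bs <- cbind(data.frame(istart = iv$istart, istop = iv$istop,
                           start_tick = start_tick, stop_tick = stop_tick,
                           t_start = start_tick * unit,
                           t_stop = stop_tick * unit,
                           width = (stop_tick - start_tick) * unit),
                burst_raw_counts(spot, start_tick, stop_tick, alternated))
  }
  structure(bs, params = params, reference = sel, spot = spot_index,
            class = c("burst_set", "data.frame"))
}

#' Burst search on a measurement
#'
#' Runs the sliding-window search on the selected photon stream of every
#' spot. The rate threshold is either `F` times the local background rate
#' of that stream (requires [estimate_background()] to have been run) or a
#' fixed rate `min_rate_cps`; exactly one of the two may be given (default
#' `F = 6`). With the background-dependent threshold every burst is
#' guaranteed a signal-to-background ratio of at least `F - 1`. Raw photon
#' counts for all canonical streams are attached to each burst by counting
#' photons inside `[t_start, t_stop]`.
#'
#' @param d A [fret_data()] measurement.
#' @param m Photons per sliding window (default 10).
#' @param F Threshold multiplier over the local background rate (> 1).
#' @param min_rate_cps Fixed rate threshold, counts/s (alternative to `F`).
#' @param sel Photon stream to search ([ph_sel()]; default all photons).
#' @param L Optional minimum raw burst size (reference-stream photons);
#'   bursts smaller than `L` are dropped.
#' @return The measurement with `d$bursts` set: one `"burst_set"` data
#'   frame per spot, sorted by start time and non-overlapping, with columns
#'   `istart`, `istop` (1-based indices into the reference stream),
#'   `start_tick`, `stop_tick`, `t_start`, `t_stop`, `width` and raw counts
#'   `n_all`, `nd_raw`, `na_raw`, `naa_raw`, `nda_raw`.
#' @export
burst_search <- function(d, m = 10, F = NULL, min_rate_cps = NULL,
                         sel = ph_sel(all = TRUE), L = NULL) {
  stopifnot(inherits(d, "fret_data"), m >= 2)
  if (!is.null(F) && !is.null(min_rate_cps))
    stop("give either F or min_rate_cps, not both")
  if (is.null(F) && is.null(min_rate_cps)) F <- 6
  if (!is.null(F) && F <= 1) stop("F must be > 1")
  if (!is.null(min_rate_cps) && min_rate_cps <= 0)
    stop("min_rate_cps must be > 0")
  if (!is.null(F) && is.null(d$background))
    stop("background-dependent threshold (F) requires ",
         "estimate_background() first")
  alternated <- is_alternated(d)
  params <- list(m = m, F = F, min_rate_cps = min_rate_cps, L = L,
                 sel = sel)
  d$bursts <- lapply(seq_along(d$spots), function(i) {
    spot <- d$spots[[i]]
    ref_ticks <- stream_timestamps(spot, sel)
    ts_s <- ref_ticks * spot$timestamps_unit
    thr_fn <- if (!is.null(F)) {
      bg <- d$background[[i]]
      function(t) F * bg_rate_at(bg, sel, t)
    } else {
      function(t) rep(min_rate_cps, length(t))
    }
    iv <- sliding_window_search(ts_s, m, thr_fn)
    if (!is.null(L) && nrow(iv) > 0)
      iv <- iv[iv$istop - iv$istart + 1 >= L, , drop = FALSE]
    make_burst_set(spot, iv, ref_ticks, sel, params, i, alternated)
  })
  d
}

#' @export
print.burst_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<burst_set> %d bursts (spot %d, stream %s, m=%d, %s)\n",
              nrow(x), attr(x, "spot"),
              stream_label(attr(x, "reference")), p$m,
              if (!is.null(p$F)) sprintf("F=%g", p$F)
              else sprintf("min_rate=%g cps", p$min_rate_cps)))
  if (nrow(x) > 0)
    cat(sprintf("  size (all): median %.0f, max %.0f; width: median %.2f ms\n",
                stats::median(x$n_all), max(x$n_all),
                stats::median(x$width) * 1e3))
  invisible(x)
}

#' Dual-channel (AND-gate) burst search
#'
#' Runs [burst_search()] independently on two photon streams and keeps the
#' pairwise time intersections of their burst intervals, implementing an
#' AND logic. The default streams are the classical dual-channel burst
#' search (DCBS) pair: all donor-excitation photons and
#' acceptor-emission-during-acceptor-excitation. Intersections are
#' re-indexed onto the all-photons stream and all counts recomputed on the
#' intersected intervals. Helps rejecting photophysical artifacts
#' (donor-only / acceptor-only or blinking molecules).
#'
#' @inheritParams burst_search
#' @param sel1,sel2 The two photon streams.
#' @return The measurement with `d$bursts` set (reference stream: all
#'   photons).
#' @export
burst_search_and_gate <- function(d, m = 10, F = 6,
                                  sel1 = ph_sel(dex = c("Dem", "Aem")),
                                  sel2 = ph_sel(aex = "Aem")) {
  d1 <- burst_search(d, m = m, F = F, sel = sel1)
  d2 <- burst_search(d, m = m, F = F, sel = sel2)
  alternated <- is_alternated(d)
  sel_all <- ph_sel(all = TRUE)
  params <- list(m = m, F = F, min_rate_cps = NULL, L = NULL,
                 sel = sel_all, and_gate = list(sel1 = sel1, sel2 = sel2))
  d$bursts <- lapply(seq_along(d$spots), function(i) {
    b1 <- d1$bursts[[i]]; b2 <- d2$bursts[[i]]
    iv <- intersect_intervals(b1$start_tick, b1$stop_tick,
                              b2$start_tick, b2$stop_tick)
    spot <- d$spots[[i]]
    all_ticks <- spot$timestamps
    # index intervals onto the all-photons stream
    istart <- findInterval(iv$start - 0.5, all_ticks) + 1L
    istop <- findInterval(iv$stop, all_ticks)
    keep <- istop >= istart
    ividx <- data.frame(istart = istart[keep], istop = istop[keep])
    make_burst_set(spot, ividx, all_ticks, sel_all, params, i, alternated)
  })
  d
}

#' Pairwise intersection of two sorted disjoint interval sets
#' @keywords internal
intersect_intervals <- function(s1, e1, s2, e2) {
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= length(s1) && j <= length(s2)) {
    lo <- max(s1[i], s2[j]); hi <- min(e1[i], e2[j])
    if (lo <= hi) { out_s <- c(out_s, lo); out_e <- c(out_e, hi) }
    if (e1[i] < e2[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, stop = out_e)
}

#' Re-index bursts onto another photon stream
#'
#' Rewrites each burst's `istart`/`istop` as indices of the first and last
#' photon of the `target` stream falling inside `[t_start, t_stop]`.
#' Bursts containing no target photon are flagged in the `empty` column.
#'
#' @param bursts A `"burst_set"`.
#' @param spot The [photon_data()] the bursts belong to.
#' @param target A [ph_sel()] stream (must select a subset of the
#'   reference stream's photons).
#' @return The `burst_set` with updated indices and a logical `empty`
#'   column.
#' @export
recompute_index <- function(bursts, spot, target) {
  stopifnot(inherits(bursts, "burst_set"), inherits(spot, "photon_data"))
  tt <- stream_timestamps(spot, target)
  istart <- findInterval(bursts$start_tick - 0.5, tt) + 1L
  istop <- findInterval(bursts$stop_tick, tt)
  bursts$istart <- istart
  bursts$istop <- istop
  bursts$empty <- istop < istart
  attr(bursts, "reference") <- target
  bursts
}

#' Audit burst threshold ratios
#'
#' Definitional audit of a background-threshold (`F`-mode) burst search:
#' for each burst, recomputes the `m`-photon local rate
#' `m / (ts[i + m - 1] - ts[i])` of each of its valid triggering windows,
#' divides by the background rate at the window start, and returns the
#' per-burst minimum ratio. With threshold multiplier `F`, every returned
#' value is `>= F` by construction.
#'
#' @param d A [fret_data()] after an `F`-mode [burst_search()].
#' @param spot Spot index (default 1).
#' @return Numeric vector, one minimum rate-over-background ratio per
#'   burst.
#' @export
burst_threshold_ratios <- function(d, spot = 1) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  bs <- d$bursts[[spot]]
  p <- attr(bs, "params")
  if (is.null(p$F)) stop("threshold audit requires an F-mode burst search")
  sp <- d$spots[[spot]]
  ts <- stream_timestamps(sp, attr(bs, "reference")) * sp$timestamps_unit
  bg <- d$background[[spot]]
  m <- p$m
  vapply(seq_len(nrow(bs)), function(b) {
    i0 <- bs$istart[b]; i1 <- bs$istop[b]
    starts <- i0:(i1 - m + 1)
    dt <- ts[starts + m - 1] - ts[starts]
    bgr <- bg_rate_at(bg, attr(bs, "reference"), ts[starts])
    valid <- dt <= m / (p$F * bgr)
    min((m / dt[valid]) / bgr[valid])
  }, numeric(1))
}

#' Burst table for export
#'
#' @param d A [fret_data()] with bursts.
#' @return Data frame with one row per burst across spots: `spot`,
#'   `istart`, `istop`, `t_start`, `t_stop`, `width_ms` and the raw
#'   per-stream counts.
#' @export
burst_table <- function(d) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  do.call(rbind, lapply(seq_along(d$bursts), function(i) {
    b <- d$bursts[[i]]
    if (nrow(b) == 0) return(NULL)
    data.frame(spot = i, istart = b$istart, istop = b$istop,
               t_start = b$t_start, t_stop = b$t_stop,
               width_ms = b$width * 1e3, n_all = b$n_all,
               nd_raw = b$nd_raw, na_raw = b$na_raw, naa_raw = b$naa_raw,
               nda_raw = b$nda_raw)
  }))
}
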
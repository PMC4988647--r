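#' Inter-photon delays
#'
#' Waiting times between consecutive photon timestamps, in seconds. The
#' distribution of these delays has an exponential tail whose time constant
#' is the inverse of the background rate; short delays are in excess due to
#' single-molecule bursts.
#'
#' @param ts Sorted timestamps in clock ticks.
#' @param unit Seconds per tick.
#' @return Numeric vector of length `length(ts) - 1`, all `>= 0`.
#' @export
interphoton_delays <- function(ts, unit) {
  if (length(ts) < 2) stop("need at least 2 photons to compute delays")
  diff(ts) * unit
}

#' Background rate by truncated-exponential MLE
#'
#' Maximum-likelihood estimate of the rate of a left-truncated exponential:
#' for delays `d_i >= tail_min`, the MLE is
#' `lambda = 1 / (mean(d_i | d_i >= tail_min) - tail_min)`.
#'
#' @param delays Inter-photon delays in seconds.
#' @param tail_min Truncation threshold in seconds; only delays at or above
#'   it enter the fit.
#' @param min_tail Minimum number of tail delays required (default 10).
#' @return List with `rate` (counts/s), `n_tail` (delays used) and
#'   `tail_min`.
#' @export
bg_fit_mle <- function(delays, tail_min, min_tail = 10) {
  tail <- delays[delays >= tail_min]
  if (length(tail) < min_tail)
    stop(sprintf("only %d delays >= tail_min; %d required",
                 length(tail), min_tail))
  mu <- unname(mean(tail) - tail_min)
  if (mu <= 0) stop("degenerate tail: mean delay equals tail_min")
  list(rate = 1 / mu, n_tail = length(tail), tail_min = unname(tail_min))
}

#' Background rate by least-squares fit of the delay histogram
#'
#' Histogram of the delays at or above `tail_min` in bins of `bin_width`;
#' a line is fitted to `log(counts)` versus bin center over the nonzero
#' bins, and the rate is minus the slope.
#'
#' @inheritParams bg_fit_mle
#' @param bin_width Histogram bin width in seconds.
#' @return List with `rate`, `n_tail`, `tail_min`.
#' @export
bg_fit_lsq <- function(delays, tail_min, bin_width = NULL, min_tail = 10) {
  tail <- delays[delays >= tail_min]
  if (length(tail) < min_tail)
    stop(sprintf("only %d delays >= tail_min; %d required",
                 length(tail), min_tail))
  if (is.null(bin_width)) bin_width <- (mean(tail) - tail_min) / 4
  if (bin_width <= 0) stop("degenerate tail: mean delay equals tail_min")
  nb <- ceiling((max(tail) - tail_min) / bin_width) + 1
  bin <- floor((tail - tail_min) / bin_width) + 1
  counts <- tabulate(bin, nbins = nb)
  centers <- tail_min + (seq_len(nb) - 0.5) * bin_width
  keep <- counts > 0
  if (sum(keep) < 3)
    stop("fewer than 3 nonzero histogram bins in the tail")
  fit <- stats::lm(log(counts[keep]) ~ centers[keep])
  rate <- -unname(stats::coef(fit)[2])
  if (!is.finite(rate) || rate <= 0)
    stop("least-squares tail fit did not yield a positive rate")
  list(rate = rate, n_tail = length(tail), tail_min = tail_min)
}

#' Automatic tail threshold for background fitting
#'
#' Iterative heuristic for choosing the minimum delay above which the
#' inter-photon delay distribution is treated as purely exponential
#' (background only). Starting from `T0 = 10 * median(delays)`, it
#' alternates a truncated-exponential MLE at the current threshold with the
#' update `T <- c / rate` (default `c = 3`, i.e. the threshold sits three
#' mean background delays out, where burst photons contribute negligibly),
#' until the rate changes by less than `tol` (relative) or `max_iter`
#' iterations.
#'
#' @inheritParams bg_fit_mle
#' @param c Threshold-to-mean-delay multiplier (default 3).
#' @param tol Relative convergence tolerance on the rate (default 0.01).
#' @param max_iter Maximum iterations (default 100).
#' @return The converged threshold in seconds, with the final rate fit in
#'   attribute `"fit"`.
#' @export
auto_tail_min <- function(delays, c = 3, tol = 0.01, max_iter = 100,
                          min_tail = 10) {
  if (length(delays) < 100)
    stop("automatic threshold selection needs at least 100 delays")
  t_cur <- 10 * stats::median(delays)
  rate_prev <- NA_real_
  history <- numeric(0)
  for (k in seq_len(max_iter)) {
    fit <- bg_fit_mle(delays, t_cur, min_tail = min_tail)
    history <- c(history, fit$rate)
    if (!is.na(rate_prev) &&
        abs(fit$rate - rate_prev) / rate_prev < tol) {
      return(structure(t_cur, fit = fit))
    }
    rate_prev <- fit$rate
    t_cur <- c / fit$rate
  }
  stop(paste0("automatic tail threshold did not converge after ", max_iter,
              " iterations; rate iterates: ",
              paste(signif(utils::tail(history, 5), 6), collapse = ", ")))
}

bg_default_streams <- function(d) {
  if (is_alternated(d)) {
    c(canonical_streams(TRUE)[c("all", "DexDem", "DexAem", "AexAem")],
      list(DexDAem = ph_sel(dex = c("Dem", "Aem"))))
  } else {
    canonical_streams(FALSE)
  }
}

#' Window edges for background periods
#' @keywords internal
bg_period_edges <- function(duration, window_s) {
  n_full <- floor(duration / window_s)
  if (n_full == 0) return(list(starts = 0, stops = duration))
  rem <- duration - n_full * window_s
  if (rem >= window_s / 2) {
    starts <- (0:n_full) * window_s
    stops <- c((1:n_full) * window_s, duration)
  } else {
    starts <- (0:(n_full - 1)) * window_s
    stops <- c(seq_len(n_full - 1) * window_s, duration)
  }
  list(starts = starts, stops = stops)
}

#' Estimate background rates per stream and time window
#'
#' Splits the acquisition into consecutive *background periods* of
#' `window_s` seconds (a final partial window shorter than `window_s / 2`
#' is merged into the previous one) and fits the exponential tail of the
#' inter-photon delay distribution of each stream within each window.
#' Windows with too few photons for a fit inherit the neighboring window's
#' estimate, with a warning.
#'
#' @param d A [fret_data()] measurement (alternation applied when
#'   period-specific streams are requested).
#' @param window_s Background period duration in seconds (default 30).
#' @param tail_min Truncation threshold: `"auto"` (default, see
#'   [auto_tail_min()]), a scalar in seconds, or a named vector/list giving
#'   per-stream thresholds keyed by stream label.
#' @param method `"mle"` (default) or `"lsq"`.
#' @param streams List of [ph_sel()] streams to estimate. Default: all,
#'   DexDem, DexAem, AexAem and DexDAem (i.e. all donor-excitation photons)
#'   for ALEX data; all, Dem, Aem otherwise.
#' @param min_tail Minimum tail delays per fit (default 10).
#' @return The measurement with `d$background` set: per spot an object of
#'   class `"bg_estimate"` with fields `window_s`, `n_periods`, `starts`,
#'   `stops`, `rates`, `thresholds`, `n_tail` (each a per-stream list of
#'   per-period vectors) and `method`.
#' @export
estimate_background <- function(d, window_s = 30, tail_min = "auto",
                                method = c("mle", "lsq"), streams = NULL,
                                min_tail = 10) {
  stopifnot(inherits(d, "fret_data"))
  method <- match.arg(method)
  if (is.null(streams)) streams <- bg_default_streams(d)
  alternated <- is_alternated(d)
  labels <- vapply(streams, stream_label, character(1),
                   alternated = alternated)
  names(streams) <- labels
  fitter <- if (method == "mle") bg_fit_mle else bg_fit_lsq
  d$background <- lapply(d$spots, function(spot) {
    edges <- bg_period_edges(acquisition_duration(spot), window_s)
    np <- length(edges$starts)
    rates <- thresholds <- ntail <- list()
    for (lab in labels) {
      ts_s <- stream_timestamps(spot, streams[[lab]], units = "s")
      r <- th <- nt <- rep(NA_real_, np)
      for (p in seq_len(np)) {
        in_win <- ts_s >= edges$starts[p] & ts_s < edges$stops[p] |
          (p == np & ts_s == edges$stops[p])
        dl <- diff(ts_s[in_win])
        tm <- if (is.character(tail_min) && identical(tail_min, "auto")) {
          "auto"
        } else if (length(tail_min) > 1 || is.list(tail_min)) {
          if (is.null(names(tail_min)) || !(lab %in% names(tail_min)))
            stop("per-stream tail_min must be named by stream label ",
                 "(missing: ", lab, ")")
          tmv <- tail_min[[lab]]
          if (identical(tmv, "auto")) "auto" else as.numeric(tmv)
        } else as.numeric(tail_min)
        fit <- tryCatch({
          if (identical(tm, "auto")) {
            thr <- auto_tail_min(dl, min_tail = min_tail)
            attr(thr, "fit")
          } else {
            fitter(dl, tm, min_tail = min_tail)
          }
        }, error = function(e) e)
        if (inherits(fit, "error")) {
          r[p] <- NA_real_
        } else {
          r[p] <- fit$rate; th[p] <- fit$tail_min; nt[p] <- fit$n_tail
        }
      }
      if (anyNA(r)) {
        bad <- which(is.na(r))
        if (length(bad) == np)
          stop("background estimation failed in every window for stream ",
               lab)
        warning(sprintf(
          "stream %s: %d window(s) with too few photons; using the %s",
          lab, length(bad), "neighboring window's estimate"))
        for (p in bad) {
          src <- if (any(!is.na(r[seq_len(p)]))) max(which(!is.na(r[seq_len(p)])))
                 else min(which(!is.na(r)))
          r[p] <- r[src]; th[p] <- th[src]; nt[p] <- nt[src]
        }
      }
      rates[[lab]] <- r; thresholds[[lab]] <- th; ntail[[lab]] <- nt
    }
    structure(list(window_s = window_s, n_periods = np,
                   starts = edges$starts, stops = edges$stops,
                   rates = rates, thresholds = thresholds, n_tail = ntail,
                   method = method, alternated = alternated),
              class = "bg_estimate")
  })
  d
}

#' @export
print.bg_estimate <- function(x, ...) {
  cat(sprintf("<bg_estimate> %d period(s) of %.3g s, method %s\n",
              x$n_periods, x$window_s, x$method))
  for (lab in names(x$rates))
    cat(sprintf("  %-8s mean %.1f cps (range %.1f-%.1f)\n", lab,
                mean(x$rates[[lab]]), min(x$rates[[lab]]),
                max(x$rates[[lab]])))
  invisible(x)
}

#' Background rate at a given time
#'
#' Looks up the background rate of the window containing `t` for the given
#' stream. Streams that were not estimated directly are decomposed into
#' canonical cells and the component rates are summed. A time exactly on a
#' window edge belongs to the later window.
#'
#' @param bg A `"bg_estimate"` (one spot's entry of `d$background`).
#' @param sel A [ph_sel()] stream.
#' @param t Time(s) in seconds from acquisition start.
#' @return Numeric vector of rates (counts/s), one per element of `t`.
#' @export
bg_rate_at <- function(bg, sel, t) {
  stopifnot(inherits(bg, "bg_estimate"))
  lab <- stream_label(sel, alternated = bg$alternated)
  idx <- pmin(pmax(findInterval(t, bg$starts), 1), bg$n_periods)
  if (lab %in% names(bg$rates)) return(bg$rates[[lab]][idx])
  # decompose into canonical cells and sum
  cells <- c(if (length(sel$dex) && !sel$all) paste0(
               if (bg$alternated) "Dex" else "", sel$dex),
             if (sel$all) names(canonical_streams(bg$alternated))[-1],
             if (length(sel$aex) && !sel$all && bg$alternated)
               paste0("Aex", sel$aex))
  if (!all(cells %in% names(bg$rates)))
    stop("stream ", lab, " was not estimated and cannot be decomposed ",
         "into estimated components")
  Reduce(`+`, lapply(cells, function(cl) bg$rates[[cl]][idx]))
}

#' Background table
#'
#' Flat per-spot, per-stream, per-period table of background estimates,
#' suitable for CSV export.
#'
#' @param d A [fret_data()] with background estimated.
#' @return A data frame with columns `spot`, `stream`, `period`, `t_start`,
#'   `t_stop`, `rate_cps`, `tail_min_us`, `n_tail`.
#' @export
bg_table <- function(d) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$background))
  do.call(rbind, lapply(seq_along(d$background), function(i) {
    bg <- d$background[[i]]
    do.call(rbind, lapply(names(bg$rates), function(lab) {
      data.frame(spot = i, stream = lab, period = seq_len(bg$n_periods),
                 t_start = bg$starts, t_stop = bg$stops,
                 rate_cps = bg$rates[[lab]],
                 tail_min_us = bg$thresholds[[lab]] * 1e6,
                 n_tail = bg$n_tail[[lab]])
    }))
  }))
}
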
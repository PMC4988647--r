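#' Laser alternation specification
#'
#' Defines how the excitation alternates between donor and acceptor lasers.
#' For us-ALEX (CW lasers alternated on microsecond timescales) the
#' excitation period of a photon is its timestamp modulo the alternation
#' `period`, in clock ticks. For ns-ALEX (interleaved pulsed lasers) the
#' period is read from the TCSPC nanotime, in TDC bins. `D_ON` and `A_ON`
#' are half-open `[start, stop)` ranges within `[0, period)`; the half-open
#' convention avoids double-counting boundary phases.
#'
#' @param mode `"none"`, `"us_alex"` or `"ns_alex"`.
#' @param period Alternation period: clock ticks (us-ALEX) or the TCSPC
#'   histogram span in TDC bins (ns-ALEX).
#' @param D_ON,A_ON Integer pairs `c(start, stop)` delimiting the donor and
#'   acceptor excitation periods. Must not overlap.
#' @return An object of class `"alt_spec"`.
#' @examples
#' alternation("us_alex", period = 4000, D_ON = c(2100, 3900),
#'             A_ON = c(100, 1900))
#' @export
alternation <- function(mode = c("none", "us_alex", "ns_alex"),
                        period = NULL, D_ON = NULL, A_ON = NULL) {
  mode <- match.arg(mode)
  if (mode == "none")
    return(structure(list(mode = "none", period = NULL, D_ON = NULL,
                          A_ON = NULL), class = "alt_spec"))
  if (is.null(period) || is.null(D_ON) || is.null(A_ON))
    stop("period, D_ON and A_ON are required for mode ", mode)
  period <- as.numeric(period)
  D_ON <- as.numeric(D_ON); A_ON <- as.numeric(A_ON)
  if (period <= 0) stop("alternation period must be > 0")
  for (rg in list(D_ON = D_ON, A_ON = A_ON)) {
    if (length(rg) != 2 || rg[1] < 0 || rg[1] >= rg[2] || rg[2] > period)
      stop("excitation ranges must satisfy 0 <= start < stop <= period")
  }
  # half-open ranges overlap iff each starts before the other stops
  if (D_ON[1] < A_ON[2] && A_ON[1] < D_ON[2])
    stop("D_ON and A_ON ranges overlap")
  structure(list(mode = mode, period = period, D_ON = D_ON, A_ON = A_ON),
            class = "alt_spec")
}

#' @export
print.alt_spec <- function(x, ...) {
  if (x$mode == "none") {
    cat("<alternation> none\n")
  } else {
    cat(sprintf("<alternation> %s  period %g  D_ON [%g, %g)  A_ON [%g, %g)\n",
                x$mode, x$period, x$D_ON[1], x$D_ON[2], x$A_ON[1], x$A_ON[2]))
  }
  invisible(x)
}

#' Per-spot photon data
#'
#' Container for the photon record of one excitation spot: sorted integer
#' timestamps (clock ticks), per-photon detector labels, optional TCSPC
#' nanotimes, and the alternation specification.
#'
#' @param timestamps Sorted non-decreasing integer-valued vector of photon
#'   arrival times in clock ticks (0-based at acquisition start).
#' @param detectors Character (or factor) vector of per-photon emission
#'   channels, values in `c("Dem", "Aem")`.
#' @param timestamps_unit Seconds per clock tick (> 0; typically 10-50 ns).
#' @param nanotimes Optional integer vector of TCSPC bins, same length.
#' @param alternation An [alternation()] spec (default: none).
#' @return An object of class `"photon_data"`. The `excitation` field
#'   (per-photon `"Dex"`/`"Aex"` label) is `NULL` until
#'   [apply_alternation()] is called.
#' @export
photon_data <- function(timestamps, detectors, timestamps_unit,
                        nanotimes = NULL,
                        alternation = phburst::alternation("none")) {
  timestamps <- as.numeric(timestamps)
  detectors <- as.character(detectors)
  if (length(timestamps) != length(detectors))
    stop("timestamps and detectors must have equal length")
  if (is.unsorted(timestamps))
    stop("timestamps must be sorted non-decreasing")
  if (!all(detectors %in% c("Dem", "Aem")))
    stop("detectors must be \"Dem\" or \"Aem\"")
  if (!is.numeric(timestamps_unit) || timestamps_unit <= 0)
    stop("timestamps_unit must be a positive number (seconds per tick)")
  if (!is.null(nanotimes)) {
    nanotimes <- as.numeric(nanotimes)
    if (length(nanotimes) != length(timestamps))
      stop("nanotimes must have the same length as timestamps")
  }
  stopifnot(inherits(alternation, "alt_spec"))
  structure(list(timestamps = timestamps, detectors = detectors,
                 timestamps_unit = as.numeric(timestamps_unit),
                 nanotimes = nanotimes, alternation = alternation,
                 excitation = NULL),
            class = "photon_data")
}

#' @export
print.photon_data <- function(x, ...) {
  cat(sprintf("<photon_data> %d photons, unit %.3g s/tick, span %.3f s\n",
              length(x$timestamps), x$timestamps_unit,
              if (length(x$timestamps)) diff(range(x$timestamps)) *
                x$timestamps_unit else 0))
  print(x$alternation)
  invisible(x)
}

#' Acquisition duration of a spot, in seconds
#' @param spot A [photon_data()] object.
#' @return Time of the last photon, seconds from acquisition start.
#' @export
acquisition_duration <- function(spot) {
  if (length(spot$timestamps) == 0) return(0)
  spot$timestamps[length(spot$timestamps)] * spot$timestamps_unit
}

#' Measurement container
#'
#' The top-level container of a burst analysis: one [photon_data()] per
#' excitation spot, plus analysis state filled in by the pipeline stages
#' ([estimate_background()], [burst_search()], ...) and the correction
#' coefficients (`gamma`, `leakage`, `dir_ex`; defaults 1, 0, 0).
#'
#' @param spots A [photon_data()] object or a list of them.
#' @param metadata Free-form description list.
#' @return An object of class `"fret_data"` with fields `spots`, `metadata`,
#'   `alternation_applied`, `background`, `bursts`, `gamma`, `leakage`,
#'   `dir_ex`.
#' @export
fret_data <- function(spots, metadata = list()) {
  if (inherits(spots, "photon_data")) spots <- list(spots)
  stopifnot(length(spots) >= 1,
            all(vapply(spots, inherits, logical(1), "photon_data")))
  structure(list(spots = spots, metadata = metadata,
                 alternation_applied = FALSE,
                 background = NULL, bursts = NULL,
                 gamma = 1, leakage = 0, dir_ex = 0),
            class = "fret_data")
}

#' @export
print.fret_data <- function(x, ...) {
  cat(sprintf("<fret_data> %d spot(s)\n", length(x$spots)))
  for (i in seq_along(x$spots)) {
    s <- x$spots[[i]]
    cat(sprintf("  spot %d: %d photons (%s), %.1f s\n", i,
                length(s$timestamps), s$alternation$mode,
                acquisition_duration(s)))
  }
  cat(sprintf("  alternation applied: %s\n", x$alternation_applied))
  cat(sprintf("  background: %s, bursts: %s\n",
              if (is.null(x$background)) "none" else "estimated",
              if (is.null(x$bursts)) "none" else
                paste(vapply(x$bursts, nrow, integer(1)), collapse = "/")))
  cat(sprintf("  gamma %.3g, leakage %.3g, dir_ex %.3g\n",
              x$gamma, x$leakage, x$dir_ex))
  invisible(x)
}

#' Is the measurement alternated (ALEX)?
#' @param d A [fret_data()] object.
#' @return Logical.
#' @export
is_alternated <- function(d) {
  d$spots[[1]]$alternation$mode != "none"
}

#' Set FRET correction coefficients
#'
#' Stores the gamma factor, donor leakage and acceptor direct-excitation
#' coefficients on the measurement. They are used by [burst_counts()],
#' [burst_size()] and the selection/weighting helpers.
#'
#' @param d A [fret_data()] object.
#' @param gamma Gamma factor (> 0): relative quantum-yield x detection
#'   efficiency of the acceptor vs donor channel.
#' @param leakage Fraction of donor emission detected in the acceptor
#'   channel (0 <= leakage < 1).
#' @param dir_ex Acceptor direct-excitation coefficient, expressed relative
#'   to the acceptor-excitation counts `naa` (0 <= dir_ex < 1).
#' @return The updated `fret_data` object.
#' @export
set_corrections <- function(d, gamma = NULL, leakage = NULL, dir_ex = NULL) {
  stopifnot(inherits(d, "fret_data"))
  if (!is.null(gamma)) {
    if (gamma <= 0) stop("gamma must be > 0")
    d$gamma <- gamma
  }
  if (!is.null(leakage)) {
    if (leakage < 0 || leakage >= 1) stop("leakage must be in [0, 1)")
    d$leakage <- leakage
  }
  if (!is.null(dir_ex)) {
    if (dir_ex < 0 || dir_ex >= 1) stop("dir_ex must be in [0, 1)")
    d$dir_ex <- dir_ex
  }
  d
}

#' Alternation phase of each photon
#'
#' For us-ALEX the phase is `timestamp %% period`; for ns-ALEX it is the
#' photon nanotime.
#' @param spot A [photon_data()] object with alternation defined.
#' @return Numeric vector of phases.
#' @keywords internal
alternation_phase <- function(spot) {
  alt <- spot$alternation
  switch(alt$mode,
         none = stop("no alternation defined"),
         us_alex = spot$timestamps %% alt$period,
         ns_alex = {
           if (is.null(spot$nanotimes))
             stop("ns-ALEX alternation requires nanotimes")
           spot$nanotimes
         })
}

#' Alternation histogram
#'
#' Histogram of photon phases within the alternation period (timestamps
#' modulo the period for us-ALEX; nanotimes for ns-ALEX), computed
#' separately per detector channel. Used to choose/inspect the `D_ON` and
#' `A_ON` excitation period definitions.
#'
#' @param spot A [photon_data()] with `us_alex` or `ns_alex` alternation.
#' @param n_bins Number of equal-width bins over `[0, period)`.
#' @return A list with `bin_edges` (length `n_bins + 1`) and `counts`, a
#'   named list of per-channel count vectors (`Dem`, `Aem`).
#' @export
alternation_histogram <- function(spot, n_bins = 100) {
  stopifnot(inherits(spot, "photon_data"), n_bins >= 1)
  phase <- alternation_phase(spot)
  period <- spot$alternation$period
  edges <- seq(0, period, length.out = n_bins + 1)
  bin <- pmin(floor(phase / period * n_bins) + 1, n_bins)
  counts <- lapply(c(Dem = "Dem", Aem = "Aem"), function(ch) {
    tabulate(bin[spot$detectors == ch], nbins = n_bins)
  })
  list(bin_edges = edges, counts = counts)
}

#' Apply the alternation period definition
#'
#' Labels each photon by its excitation period (`Dex` when its phase falls
#' in `D_ON`, `Aex` when in `A_ON`) and removes photons outside both
#' ranges. After this, period-specific photon streams become available.
#' The operation is one-shot: re-applying requires reloading the data.
#'
#' @param d A [fret_data()] object whose spots all have a valid
#'   alternation spec.
#' @return The updated `fret_data` with `alternation_applied = TRUE`.
#' @export
apply_alternation <- function(d) {
  stopifnot(inherits(d, "fret_data"))
  if (d$alternation_applied)
    stop("alternation already applied; the data file will need to be ",
         "reloaded to change the period definitions")
  d$spots <- lapply(d$spots, function(spot) {
    alt <- spot$alternation
    phase <- alternation_phase(spot)  # errors for mode "none"
    in_d <- phase >= alt$D_ON[1] & phase < alt$D_ON[2]
    in_a <- phase >= alt$A_ON[1] & phase < alt$A_ON[2]
    keep <- in_d | in_a
    spot$timestamps <- spot$timestamps[keep]
    spot$detectors <- spot$detectors[keep]
    if (!is.null(spot$nanotimes)) spot$nanotimes <- spot$nanotimes[keep]
    spot$excitation <- ifelse(in_d[keep], "Dex", "Aex")
    spot
  })
  d$alternation_applied <- TRUE
  d
}
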
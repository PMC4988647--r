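#' Shot-noise-limited standard deviation of sub-burst FRET
#'
#' For a static FRET population the acceptor count of an n-photon chunk is
#' binomial with success probability the population proximity ratio
#' `E_p`, so the chunk FRET estimate has standard deviation
#' `sqrt(E_p * (1 - E_p) / n)`.
#'
#' @param E_p Proximity ratio in `[0, 1]`.
#' @param n Photons per sub-burst (`>= 1`).
#' @return Numeric vector of standard deviations.
#' @export
shot_noise_std <- function(E_p, n) {
  stopifnot(all(E_p >= 0 & E_p <= 1), n >= 1)
  sqrt(E_p * (1 - E_p) / n)
}

#' Burst variance analysis
#'
#' Divides each burst into consecutive non-overlapping sub-bursts of
#' exactly `n` donor-excitation photons (starting at the burst's first
#' Dex photon; a trailing remainder shorter than `n` is dropped), computes
#' the proximity ratio of each sub-burst as the fraction of
#' acceptor-emission photons, and summarizes each burst by the mean
#' (`E_avg`) and the population standard deviation (`s_E`, denominator
#' `n_chunks`) of its sub-burst values. Bursts with fewer than 2 chunks
#' are excluded (a message reports how many). Background photons inside
#' chunks are neglected, a good approximation at typical
#' signal-to-background ratios. On static data `s_E` scatters around
#' [shot_noise_std()]; millisecond interconversion pushes it above the
#' curve.
#'
#' @param d A [fret_data()] with bursts (alternation applied for ALEX
#'   data).
#' @param n Photons per sub-burst (default 7; must be `>= 2`).
#' @param spot Spot index.
#' @return Data frame of class `"bva_result"`: `burst`, `E_avg`, `s_E`,
#'   `n_chunks`; attribute `n`.
#' @export
bva <- function(d, n = 7, spot = 1) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  if (n < 2) stop("n must be >= 2")
  sp <- d$spots[[spot]]
  dex_all <- ph_sel(dex = c("Dem", "Aem"))
  bursts_d <- recompute_index(d$bursts[[spot]], sp, dex_all)
  # acceptor mask reduced onto the Dex photon stream
  aem_mask_d <- stream_mask(sp, ph_sel(dex = "Aem"))[
    stream_mask(sp, dex_all)]
  res <- lapply(seq_len(nrow(bursts_d)), function(b) {
    if (isTRUE(bursts_d$empty[b])) return(NULL)
    i0 <- bursts_d$istart[b]; i1 <- bursts_d$istop[b]
    n_ph <- i1 - i0 + 1
    n_chunks <- n_ph %/% n
    if (n_chunks < 2) return(data.frame(burst = b, E_avg = NA_real_,
                                        s_E = NA_real_,
                                        n_chunks = n_chunks))
    starts <- i0 + (seq_len(n_chunks) - 1) * n
    e_sub <- vapply(starts, function(s0)
      sum(aem_mask_d[s0:(s0 + n - 1)]) / n, numeric(1))
    data.frame(burst = b, E_avg = mean(e_sub),
               s_E = sqrt(sum((e_sub - mean(e_sub))^2) / n_chunks),
               n_chunks = n_chunks)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(burst = integer(0),
                                      E_avg = numeric(0), s_E = numeric(0),
                                      n_chunks = integer(0))
  n_dropped <- sum(is.na(out$s_E))
  if (n_dropped > 0)
    message(n_dropped, " burst(s) with fewer than 2 sub-bursts excluded")
  out <- out[!is.na(out$s_E), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n = n, class = c("bva_result", "data.frame"))
}

#' Flag bursts above the shot-noise curve
#'
#' Simple indicator for dynamics: a burst is flagged when its sub-burst
#' standard deviation exceeds the shot-noise expectation at its own mean
#' FRET, `s_E > shot_noise_std(E_avg, n) + margin`. On static data the
#' flagged fraction scatters around one half (the statistic fluctuates
#' symmetrically about the curve for bursts with many chunks); dynamic
#' populations push it towards 1. This decision rule is a convenience
#' addition of this package, not a hypothesis test.
#'
#' @param result A `"bva_result"`.
#' @param margin Optional offset added to the curve before comparison
#'   (default 0).
#' @return The input with a logical `above` column; attribute
#'   `fraction_above`.
#' @export
bva_dynamic_flag <- function(result, margin = 0) {
  stopifnot(inherits(result, "bva_result"))
  n <- attr(result, "n")
  above <- if (nrow(result) > 0)
    result$s_E > shot_noise_std(result$E_avg, n) + margin else logical(0)
  result$above <- above
  attr(result, "fraction_above") <-
    if (length(above) > 0) mean(above) else NA_real_
  result
}

#' BVA export table and 2-D histogram grid
#'
#' @param result A `"bva_result"`.
#' @param e_binwidth,s_binwidth Bin widths for the `E_avg` x `s_E` grid.
#' @return List with `table` (the per-burst data frame) and `grid` (counts
#'   matrix with E bins on rows, s_E bins on columns, bin edges in
#'   `dimnames`).
#' @export
bva_grid <- function(result, e_binwidth = 0.05, s_binwidth = 0.025) {
  stopifnot(inherits(result, "bva_result"))
  e_edges <- seq(0, 1 + e_binwidth, by = e_binwidth)
  s_edges <- seq(0, 0.5 + s_binwidth, by = s_binwidth)
  ei <- pmin(pmax(findInterval(result$E_avg, e_edges), 1),
             length(e_edges) - 1)
  si <- pmin(pmax(findInterval(result$s_E, s_edges), 1),
             length(s_edges) - 1)
  grid <- matrix(0L, length(e_edges) - 1, length(s_edges) - 1,
                 dimnames = list(utils::head(e_edges, -1),
                                 utils::head(s_edges, -1)))
  for (i in seq_along(ei)) grid[ei[i], si[i]] <- grid[ei[i], si[i]] + 1L
  list(table = as.data.frame(result), grid = grid)
}
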
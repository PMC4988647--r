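#' Background-correct raw burst counts
#'
#' Subtracts the expected background counts `rate * width` from each raw
#' per-stream burst count, using the background rate of the period
#' containing the burst start. Corrected counts are real-valued and may be
#' slightly negative; they are never clamped during computation (clamping
#' would bias downstream averages).
#'
#' @param bursts A `"burst_set"`.
#' @param bg The spot's `"bg_estimate"`.
#' @return Data frame with columns `nd`, `na`, `naa`, `nda`
#'   (background-corrected; `naa`/`nda` are `NA` for non-ALEX data).
#' @export
background_correct <- function(bursts, bg) {
  stopifnot(inherits(bursts, "burst_set"), inherits(bg, "bg_estimate"))
  alt <- bg$alternated
  streams <- if (alt) {
    list(nd = ph_sel(dex = "Dem"), na = ph_sel(dex = "Aem"),
         naa = ph_sel(aex = "Aem"), nda = ph_sel(aex = "Dem"))
  } else {
    list(nd = ph_sel(dex = "Dem"), na = ph_sel(dex = "Aem"))
  }
  raw <- list(nd = bursts$nd_raw, na = bursts$na_raw,
              naa = bursts$naa_raw, nda = bursts$nda_raw)
  out <- data.frame(nd = rep(NA_real_, nrow(bursts)), na = NA_real_,
                    naa = NA_real_, nda = NA_real_)
  for (nm in names(streams)) {
    # nda only contains background and is conventionally neglected; leave
    # it NA rather than fail when its stream was never estimated
    rate <- tryCatch(bg_rate_at(bg, streams[[nm]], bursts$t_start),
                     error = function(e) {
                       if (nm == "nda") return(NULL)
                       stop(e)
                     })
    if (!is.null(rate)) out[[nm]] <- raw[[nm]] - rate * bursts$width
  }
  out
}

#' Leakage and direct-excitation correction of acceptor counts
#'
#' Removes from the donor-excitation acceptor counts the donor leakage
#' (`leakage * nd`) and the directly excited acceptor contribution
#' (`dir_ex * naa`; the direct-excitation coefficient is expressed
#' relative to the acceptor-excitation counts). `nd` and `naa` are
#' unaffected.
#'
#' @param nd,na,naa Background-corrected counts (vectors).
#' @param leakage,dir_ex Correction coefficients.
#' @return The corrected `na` vector.
#' @export
leakage_direx_correct <- function(nd, na, naa, leakage = 0, dir_ex = 0) {
  dirc <- if (is.null(naa) || all(is.na(naa))) 0 else dir_ex * naa
  na - leakage * nd - dirc
}

#' Gamma-corrected burst size
#'
#' `na + gamma * nd` (donor-excitation size) or
#' `na + gamma * nd + naa` (total size, `add_naa = TRUE`).
#'
#' @param nd,na,naa Corrected counts.
#' @param gamma Gamma factor.
#' @param add_naa Include acceptor-excitation counts.
#' @return Numeric vector of sizes.
#' @export
burst_size <- function(nd, na, naa = 0, gamma = 1, add_naa = FALSE) {
  size <- na + gamma * nd
  if (add_naa) size <- size + naa
  size
}

#' Proximity ratio
#'
#' `E_pr = na / (na + nd)` computed from background-corrected counts, with
#' no gamma, leakage or direct-excitation correction applied (that is the
#' definition of the proximity ratio). Bursts with `na + nd <= 0` yield
#' `NA`.
#'
#' @param nd,na Background-corrected counts.
#' @return Numeric vector in (approximately) `[0, 1]`; background
#'   subtraction can overshoot slightly.
#' @export
proximity_ratio <- function(nd, na) {
  tot <- nd + na
  ifelse(tot > 0, na / tot, NA_real_)
}

#' Stoichiometry
#'
#' `S = (gamma * nd + na) / (gamma * nd + na + naa)`; with `gamma = 1`
#' this is the raw stoichiometry. Donor-only molecules sit near `S = 1`,
#' acceptor-only near `S = 0`, FRET species mid-range. Zero denominators
#' yield `NA`.
#'
#' @param nd,na,naa Corrected counts.
#' @param gamma Gamma factor (default 1: raw S).
#' @return Numeric vector.
#' @export
stoichiometry <- function(nd, na, naa, gamma = 1) {
  dex <- gamma * nd + na
  tot <- dex + naa
  ifelse(tot > 0, dex / tot, NA_real_)
}

#' Population-level FRET efficiency correction
#'
#' Converts a (background-corrected) proximity-ratio value, typically a
#' fitted population peak position, into the corrected FRET efficiency:
#' \deqn{E = \frac{E_{pr}(l + d\gamma + 1) - l - d\gamma}
#'            {E_{pr}(l - \gamma + 1) - l + \gamma}}
#' where \eqn{l} is the leakage and \eqn{d} the direct-excitation
#' coefficient in the *total-size convention* (direct-excitation counts
#' proportional to the gamma-corrected donor-excitation size; see
#' [dir_ex_total_coeff()] for conversion from the naa-based convention).
#' Reduces to `E = E_pr / (E_pr (1 - gamma) + gamma)` when
#' `leakage = dir_ex_t = 0` and to the identity when additionally
#' `gamma = 1`. Correcting fitted population values, rather than each
#' burst, avoids distorting the shape of the FRET distribution.
#'
#' @param E_pr Proximity ratio value(s).
#' @param gamma Gamma factor.
#' @param leakage Leakage coefficient.
#' @param dir_ex_t Direct-excitation coefficient, total-size convention.
#' @return Corrected FRET efficiency; `NA` where the denominator vanishes.
#' @export
correct_E_population <- function(E_pr, gamma = 1, leakage = 0,
                                 dir_ex_t = 0) {
  num <- E_pr * (leakage + dir_ex_t * gamma + 1) - leakage -
    dir_ex_t * gamma
  den <- E_pr * (leakage - gamma + 1) - leakage + gamma
  ifelse(abs(den) > 0, num / den, NA_real_)
}

#' Population-level stoichiometry correction
#'
#' Applies the counts-level corrections algebraically to a
#' (proximity ratio, raw stoichiometry) pair: with
#' `T = nd + na`, the corrected donor-excitation size is
#' `T * (E_pr - leakage (1 - E_pr) - dir_ex (1 - S) / S + gamma (1 - E_pr))`
#' and `naa = T (1 - S) / S`, giving the corrected
#' `S = size_dex / (size_dex + naa)`. `dir_ex` here uses the naa-based
#' convention, as for [leakage_direx_correct()]. Reduces to the identity
#' at `gamma = 1`, `leakage = dir_ex = 0`.
#'
#' @param E_pr Proximity ratio value(s).
#' @param S_raw Raw stoichiometry value(s) (gamma = 1, uncorrected).
#' @param gamma,leakage,dir_ex Correction coefficients (naa convention for
#'   `dir_ex`).
#' @return Corrected stoichiometry; `NA` where undefined.
#' @export
correct_S_population <- function(E_pr, S_raw, gamma = 1, leakage = 0,
                                 dir_ex = 0) {
  naa_T <- ifelse(S_raw > 0, (1 - S_raw) / S_raw, NA_real_)
  na_T <- E_pr - leakage * (1 - E_pr) - dir_ex * naa_T
  dex_T <- na_T + gamma * (1 - E_pr)
  tot <- dex_T + naa_T
  out <- ifelse(abs(tot) > 0, dex_T / tot, NA_real_)
  # A-only limit: no donor-excitation signal at all
  out[!is.na(S_raw) & S_raw == 0] <- 0
  out
}

#' Convert the direct-excitation coefficient to the total-size convention
#'
#' The counts-level correction expresses direct excitation relative to the
#' acceptor-excitation counts (`dir_ex * naa`); the closed-form
#' population-level E correction uses a coefficient relative to the
#' gamma-corrected donor-excitation size. The two are related per burst
#' by `dir_ex_t = dir_ex * naa / (na_corrected + gamma * nd)`.
#'
#' @param nd,na,naa Background-corrected counts.
#' @param gamma,leakage,dir_ex Coefficients (naa convention).
#' @return The equivalent total-size-convention coefficient(s).
#' @export
dir_ex_total_coeff <- function(nd, na, naa, gamma = 1, leakage = 0,
                               dir_ex = 0) {
  na_c <- leakage_direx_correct(nd, na, naa, leakage, dir_ex)
  dir_ex * naa / (na_c + gamma * nd)
}

#' Corrected burst counts and derived quantities
#'
#' Applies background correction (always) and the stored leakage /
#' direct-excitation / gamma coefficients to every burst of a spot, and
#' derives the proximity ratio, raw stoichiometry and gamma-corrected
#' sizes.
#'
#' @param d A [fret_data()] with background and bursts.
#' @param spot Spot index (default 1).
#' @return Data frame, one row per burst: `nd`, `na`, `naa`, `nda`
#'   (background-corrected; `na` additionally leakage/direct-excitation
#'   corrected), `E_pr`, `S_raw` (from background-corrected counts only),
#'   `size_dex`, `size_all` (gamma-corrected sizes using the corrected
#'   `na`), `width`, `t_start`.
#' @export
burst_counts <- function(d, spot = 1) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  if (is.null(d$background)) stop("estimate_background() required first")
  bs <- d$bursts[[spot]]
  bgc <- background_correct(bs, d$background[[spot]])
  na_c <- leakage_direx_correct(bgc$nd, bgc$na, bgc$naa,
                                d$leakage, d$dir_ex)
  naa0 <- ifelse(is.na(bgc$naa), 0, bgc$naa)
  data.frame(nd = bgc$nd, na = na_c, naa = bgc$naa, nda = bgc$nda,
             E_pr = proximity_ratio(bgc$nd, bgc$na),
             S_raw = stoichiometry(bgc$nd, bgc$na, bgc$naa, gamma = 1),
             size_dex = burst_size(bgc$nd, na_c, gamma = d$gamma),
             size_all = burst_size(bgc$nd, na_c, naa0, gamma = d$gamma,
                                   add_naa = TRUE),
             width = bs$width, t_start = bs$t_start)
}

#' Corrected burst table for export
#'
#' @param d A [fret_data()] with background and bursts.
#' @return Data frame across spots combining [burst_table()] positions
#'   with the corrected counts and derived quantities of [burst_counts()],
#'   including population-corrected `E_corr`/`S_corr` per burst (for
#'   display only; population-level fitting should correct fitted peaks
#'   instead).
#' @export
corrected_burst_table <- function(d) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  do.call(rbind, lapply(seq_along(d$bursts), function(i) {
    bs <- d$bursts[[i]]
    if (nrow(bs) == 0) return(NULL)
    bc <- burst_counts(d, i)
    dirt <- dir_ex_total_coeff(bc$nd, bc$na + d$leakage * bc$nd +
                                 d$dir_ex * ifelse(is.na(bc$naa), 0, bc$naa),
                               bc$naa, d$gamma, d$leakage, d$dir_ex)
    dirt[is.na(dirt)] <- 0
    data.frame(spot = i, t_start = bs$t_start, width_ms = bs$width * 1e3,
               nd = bc$nd, na = bc$na, naa = bc$naa,
               size_dex = bc$size_dex, size_all = bc$size_all,
               E_pr = bc$E_pr, S_raw = bc$S_raw,
               E_corr = correct_E_population(bc$E_pr, d$gamma, d$leakage,
                                             dirt),
               S_corr = correct_S_population(bc$E_pr, bc$S_raw, d$gamma,
                                             d$leakage, d$dir_ex))
  }))
}
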
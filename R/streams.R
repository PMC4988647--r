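#' Photon stream selection
#'
#' A photon stream is a subset of detected photons defined by emission
#' channel (donor `"Dem"` / acceptor `"Aem"`) and, for alternating-laser
#' (ALEX) data, by excitation period (donor `Dex` / acceptor `Aex`).
#' Non-ALEX data has 3 canonical streams (all, Dem, Aem); us-ALEX data has
#' 5 (all, DexDem, DexAem, AexDem, AexAem). Arbitrary unions of the
#' canonical channel-by-period cells are permitted.
#'
#' @param dex Channels selected during donor-excitation periods, a subset of
#'   `c("Dem", "Aem")`. For non-ALEX data this is the only meaningful slot.
#' @param aex Channels selected during acceptor-excitation periods.
#' @param all If `TRUE`, select every photon (shorthand; `dex`/`aex` ignored).
#' @return An object of class `"ph_sel"`.
#' @examples
#' ph_sel(all = TRUE)          # every photon
#' ph_sel(dex = "Aem")         # acceptor emission during donor excitation
#' ph_sel(dex = c("Dem", "Aem"))  # all donor-excitation photons
#' @export
ph_sel <- function(dex = character(), aex = character(), all = FALSE) {
  if (identical(dex, "all") || isTRUE(all)) {
    return(structure(list(dex = c("Dem", "Aem"), aex = c("Dem", "Aem"),
                          all = TRUE), class = "ph_sel"))
  }
  dex <- as.character(dex); aex <- as.character(aex)
  chans <- c("Dem", "Aem")
  if (!all(dex %in% chans) || !all(aex %in% chans))
    stop("stream channels must be a subset of c(\"Dem\", \"Aem\")")
  if (length(dex) == 0 && length(aex) == 0)
    stop("empty photon stream: select at least one channel/period cell")
  structure(list(dex = sort(unique(dex)), aex = sort(unique(aex)),
                 all = FALSE), class = "ph_sel")
}

#' @export
print.ph_sel <- function(x, ...) {
  cat("<ph_sel>", stream_label(x), "\n")
  invisible(x)
}

#' Canonical label of a photon stream
#'
#' @param sel A [ph_sel()] object.
#' @param alternated Logical; label in ALEX (`"DexDem"`, ...) or non-ALEX
#'   (`"Dem"`, `"Aem"`) vocabulary. Default `TRUE`.
#' @return A character scalar, e.g. `"all"`, `"DexAem"`, or a `+`-joined
#'   union label such as `"DexDem+DexAem"`.
#' @export
stream_label <- function(sel, alternated = TRUE) {
  stopifnot(inherits(sel, "ph_sel"))
  if (sel$all) return("all")
  if (!alternated) {
    if (length(sel$aex) > 0)
      stop("acceptor-excitation selection is meaningless for non-ALEX data")
    return(paste(sel$dex, collapse = "+"))
  }
  lab1 <- function(period, chans) {
    if (length(chans) == 0) return(character(0))
    paste0(period, if (length(chans) == 2) "DAem" else chans)
  }
  paste(c(lab1("Dex", sel$dex), lab1("Aex", sel$aex)), collapse = "+")
}

#' Enumerate the canonical photon streams
#'
#' @param alternated Logical; `TRUE` for ALEX data (5 streams), `FALSE` for
#'   single-laser data (3 streams).
#' @return Named list of [ph_sel()] objects.
#' @export
canonical_streams <- function(alternated = TRUE) {
  if (alternated) {
    list(all    = ph_sel(all = TRUE),
         DexDem = ph_sel(dex = "Dem"),
         DexAem = ph_sel(dex = "Aem"),
         AexDem = ph_sel(aex = "Dem"),
         AexAem = ph_sel(aex = "Aem"))
  } else {
    list(all = ph_sel(all = TRUE),
         Dem = ph_sel(dex = "Dem"),
         Aem = ph_sel(dex = "Aem"))
  }
}

#' Union of photon streams
#'
#' @param ... [ph_sel()] objects.
#' @return A [ph_sel()] selecting the union of the arguments' cells.
#' @export
ph_union <- function(...) {
  sels <- list(...)
  stopifnot(all(vapply(sels, inherits, logical(1), "ph_sel")))
  if (any(vapply(sels, function(s) s$all, logical(1)))) return(ph_sel(all = TRUE))
  ph_sel(dex = unlist(lapply(sels, `[[`, "dex")),
         aex = unlist(lapply(sels, `[[`, "aex")))
}

#' Boolean photon mask for a stream selection
#'
#' Returns a logical vector over the photons of one spot, `TRUE` exactly for
#' the photons in the selected stream. Period-specific selections require
#' the alternation definition to have been applied first (see
#' [apply_alternation()]); for non-ALEX data every photon counts as
#' donor-excited.
#'
#' @param spot A [photon_data()] object.
#' @param sel A [ph_sel()] selection.
#' @return Logical vector, one element per photon.
#' @export
stream_mask <- function(spot, sel) {
  stopifnot(inherits(spot, "photon_data"), inherits(sel, "ph_sel"))
  n <- length(spot$timestamps)
  if (sel$all) return(rep(TRUE, n))
  alt <- spot$alternation
  if (alt$mode == "none") {
    if (length(sel$aex) > 0)
      stop("period-specific selection (Aex) on non-alternation data")
    return(spot$detectors %in% sel$dex)
  }
  if (is.null(spot$excitation))
    stop("alternation defined but not applied; call apply_alternation() ",
         "before period-specific stream selection")
  (spot$excitation == "Dex" & spot$detectors %in% sel$dex) |
    (spot$excitation == "Aex" & spot$detectors %in% sel$aex)
}

#' Timestamps of a photon stream
#'
#' @inheritParams stream_mask
#' @param units `"ticks"` (raw clock units, default) or `"s"` (seconds).
#' @return Sorted numeric vector of timestamps of the selected photons.
#' @export
stream_timestamps <- function(spot, sel, units = c("ticks", "s")) {
  units <- match.arg(units)
  ts <- spot$timestamps[stream_mask(spot, sel)]
  if (units == "s") ts * spot$timestamps_unit else ts
}
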
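#' Burst selection mask
#'
#' Computes the logical keep-mask of one selection rule over the bursts of
#' one spot. Available rules (all bounds inclusive on both ends):
#' \describe{
#'   \item{`size`}{gamma-corrected burst size ([burst_size()]), with
#'     options `gamma` (default: the measurement's) and `add_naa`.}
#'   \item{`naa`}{background-corrected acceptor-excitation counts.}
#'   \item{`width`}{burst duration in seconds.}
#'   \item{`ES`}{proximity ratio and raw stoichiometry jointly inside the
#'     rectangle `E_range` x `S_range` (ALEX only).}
#' }
#'
#' @param d A [fret_data()] with bursts (and background for count-based
#'   rules).
#' @param rule Rule name: `"size"`, `"naa"`, `"width"` or `"ES"`.
#' @param th1 Lower bound (default 0).
#' @param th2 Upper bound (default `Inf`).
#' @param gamma Gamma for the size rule (default: measurement coefficient).
#' @param add_naa Include `naa` in the size (default `FALSE`).
#' @param E_range,S_range Length-2 bounds for the `ES` rule.
#' @param spot Spot index.
#' @return Logical vector over the spot's bursts.
#' @export
selection_mask <- function(d, rule, th1 = 0, th2 = Inf, gamma = NULL,
                           add_naa = FALSE, E_range = c(0, 1),
                           S_range = c(0, 1), spot = 1) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  if (th1 > th2) stop("th1 must be <= th2")
  bs <- d$bursts[[spot]]
  if (nrow(bs) == 0) return(logical(0))
  if (rule == "width") return(bs$width >= th1 & bs$width <= th2)
  bc <- burst_counts(d, spot)
  switch(rule,
    size = {
      g <- if (is.null(gamma)) d$gamma else gamma
      naa0 <- ifelse(is.na(bc$naa), 0, bc$naa)
      sz <- burst_size(bc$nd, bc$na, naa0, gamma = g, add_naa = add_naa)
      sz >= th1 & sz <= th2
    },
    naa = {
      if (!is_alternated(d)) stop("naa rule requires ALEX data")
      bc$naa >= th1 & bc$naa <= th2
    },
    ES = {
      if (!is_alternated(d)) stop("ES rule requires ALEX data")
      !is.na(bc$E_pr) & !is.na(bc$S_raw) &
        bc$E_pr >= E_range[1] & bc$E_pr <= E_range[2] &
        bc$S_raw >= S_range[1] & bc$S_raw <= S_range[2]
    },
    stop("unknown selection rule: ", rule)
  )
}

#' Select bursts
#'
#' Returns a copy of the measurement keeping, in every spot, exactly the
#' bursts whose rule statistic lies in `[th1, th2]` (see
#' [selection_mask()]). Selections share the photon data and compose:
#' chaining several `select_bursts()` calls intersects the criteria.
#'
#' @inheritParams selection_mask
#' @return The measurement with filtered `d$bursts`.
#' @examples
#' \dontrun{
#' ds <- select_bursts(d, "size", th1 = 30, add_naa = TRUE)
#' ds <- select_bursts(ds, "width", th1 = 0.5e-3, th2 = 3e-3)
#' }
#' @export
select_bursts <- function(d, rule, th1 = 0, th2 = Inf, gamma = NULL,
                          add_naa = FALSE, E_range = c(0, 1),
                          S_range = c(0, 1)) {
  stopifnot(inherits(d, "fret_data"), !is.null(d$bursts))
  d$bursts <- lapply(seq_along(d$bursts), function(i) {
    bs <- d$bursts[[i]]
    keep <- selection_mask(d, rule, th1 = th1, th2 = th2, gamma = gamma,
                           add_naa = add_naa, E_range = E_range,
                           S_range = S_range, spot = i)
    at <- attributes(bs)
    out <- bs[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "params") <- at$params
    attr(out, "reference") <- at$reference
    attr(out, "spot") <- at$spot
    class(out) <- at$class
    out
  })
  d
}
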
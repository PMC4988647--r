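#' Write a measurement to a Photon-HDF5-style file
#'
#' Writes the subset of the Photon-HDF5 layout used by this package: per
#' spot a `photon_data` group (named `photon_data` for single-spot files,
#' `photon_data0`, `photon_data1`, ... otherwise) holding `timestamps`
#' (64-bit integers), `detectors` (integer codes), optional `nanotimes`,
#' `timestamps_specs/timestamps_unit`, the detector spectral map
#' (`detectors_specs/spectral_ch1`/`spectral_ch2` = donor/acceptor code)
#' and, for ALEX data, `measurement_specs` with the measurement type,
#' alternation period and the two excitation period ranges.
#'
#' @param d A [fret_data()] measurement (alternation not yet applied;
#'   the raw photon record is written as is).
#' @param path Output file path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_photon_hdf5 <- function(d, path) {
  stopifnot(inherits(d, "fret_data"))
  if (any(vapply(d$spots, function(s) length(s$timestamps) == 0, logical(1))))
    stop("cannot write a measurement with an empty spot")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  nspots <- length(d$spots)
  for (i in seq_len(nspots)) {
    g <- if (nspots == 1) "photon_data" else sprintf("photon_data%d", i - 1)
    spot <- d$spots[[i]]
    rhdf5::h5createGroup(path, g)
    n <- length(spot$timestamps)
    rhdf5::h5createDataset(path, file.path(g, "timestamps"), dims = n,
                           H5type = "H5T_STD_I64LE")
    rhdf5::h5write(spot$timestamps, path, file.path(g, "timestamps"))
    rhdf5::h5write(ifelse(spot$detectors == "Dem", 0L, 1L), path,
                   file.path(g, "detectors"))
    if (!is.null(spot$nanotimes))
      rhdf5::h5write(as.integer(spot$nanotimes), path,
                     file.path(g, "nanotimes"))
    rhdf5::h5createGroup(path, file.path(g, "timestamps_specs"))
    rhdf5::h5write(spot$timestamps_unit, path,
                   file.path(g, "timestamps_specs/timestamps_unit"))
    rhdf5::h5createGroup(path, file.path(g, "detectors_specs"))
    rhdf5::h5write(0L, path, file.path(g, "detectors_specs/spectral_ch1"))
    rhdf5::h5write(1L, path, file.path(g, "detectors_specs/spectral_ch2"))
    alt <- spot$alternation
    rhdf5::h5createGroup(path, file.path(g, "measurement_specs"))
    mtype <- switch(alt$mode, none = "smFRET", us_alex = "smFRET-usALEX",
                    ns_alex = "smFRET-nsALEX")
    rhdf5::h5write(mtype, path,
                   file.path(g, "measurement_specs/measurement_type"))
    if (alt$mode != "none") {
      rhdf5::h5write(alt$period, path,
                     file.path(g, "measurement_specs/alex_period"))
      rhdf5::h5write(alt$D_ON, path,
                     file.path(g, "measurement_specs/alex_excitation_period1"))
      rhdf5::h5write(alt$A_ON, path,
                     file.path(g, "measurement_specs/alex_excitation_period2"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

h5_has <- function(listing, g, name) {
  any(listing$group == paste0("/", g) & listing$name == name) ||
    any(sub("^/", "", file.path(listing$group, listing$name)) ==
          file.path(g, name))
}

h5_read_req <- function(path, listing, g, name) {
  if (!h5_has(listing, g, name))
    stop(sprintf("invalid photon file: missing mandatory field /%s/%s",
                 g, name))
  rhdf5::h5read(path, file.path(g, name), bit64conversion = "double")
}

#' Read a Photon-HDF5-style file
#'
#' Reads files written by [write_photon_hdf5()] (a minimal subset of the
#' Photon-HDF5 layout). Alternation metadata is loaded but *not* applied;
#' call [apply_alternation()] to label and filter photons by excitation
#' period. Detector integer codes are mapped to `Dem`/`Aem` via the file's
#' spectral-channel map; any other code is a validation error. Unknown
#' groups are ignored with a warning.
#'
#' @param path Path to an existing file.
#' @return A [fret_data()] measurement.
#' @export
read_photon_hdf5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  listing <- rhdf5::h5ls(path)
  top <- listing$name[listing$group == "/"]
  groups <- sort(top[grepl("^photon_data[0-9]*$", top)])
  unknown <- top[!grepl("^photon_data[0-9]*$", top)]
  if (length(unknown) > 0)
    warning("ignoring unknown top-level group(s): ",
            paste(unknown, collapse = ", "))
  if (length(groups) == 0)
    stop("invalid photon file: missing mandatory group /photon_data")
  spots <- lapply(groups, function(g) {
    ts <- as.numeric(h5_read_req(path, listing, g, "timestamps"))
    if (is.unsorted(ts))
      stop("invalid photon file: unsorted timestamps in /", g)
    det_codes <- as.integer(h5_read_req(path, listing, g, "detectors"))
    unit <- as.numeric(h5_read_req(path, listing, g,
                                   "timestamps_specs/timestamps_unit"))
    ch_d <- as.integer(h5_read_req(path, listing, g,
                                   "detectors_specs/spectral_ch1"))
    ch_a <- as.integer(h5_read_req(path, listing, g,
                                   "detectors_specs/spectral_ch2"))
    if (!all(det_codes %in% c(ch_d, ch_a)))
      stop("invalid photon file: detector code(s) outside the spectral map ",
           "in /", g)
    detectors <- ifelse(det_codes == ch_d, "Dem", "Aem")
    nanotimes <- if (h5_has(listing, g, "nanotimes"))
      as.numeric(rhdf5::h5read(path, file.path(g, "nanotimes"))) else NULL
    mtype <- as.character(h5_read_req(path, listing, g,
                                      "measurement_specs/measurement_type"))
    alt <- if (mtype == "smFRET") {
      alternation("none")
    } else {
      mode <- switch(mtype, `smFRET-usALEX` = "us_alex",
                     `smFRET-nsALEX` = "ns_alex",
                     stop("unknown measurement_type: ", mtype))
      alternation(mode,
                  period = as.numeric(h5_read_req(
                    path, listing, g, "measurement_specs/alex_period")),
                  D_ON = as.numeric(h5_read_req(
                    path, listing, g,
                    "measurement_specs/alex_excitation_period1")),
                  A_ON = as.numeric(h5_read_req(
                    path, listing, g,
                    "measurement_specs/alex_excitation_period2")))
    }
    photon_data(ts, detectors, unit, nanotimes = nanotimes,
                alternation = alt)
  })
  fret_data(spots, metadata = list(source = path))
}
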
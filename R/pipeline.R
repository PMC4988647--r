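#' Validate a pipeline configuration
#'
#' Parses and type/range-checks a declarative YAML pipeline configuration,
#' filling in defaults. Unknown keys are rejected. The schema (all
#' sections optional):
#' \preformatted{
#' input: path.h5
#' alternation: {D_ON: [2100, 3900], A_ON: [100, 1900]}   # overrides
#' background: {window_s: 30, tail_min: auto, method: mle}
#' search: {m: 10, F: 6, min_rate_cps: ~, stream: all, and_gate: false,
#'          L: ~}
#' corrections: {gamma: 1, leakage: 0, dir_ex: 0}
#' selections:
#'   - {rule: size, th1: 30, add_naa: true}
#'   - {rule: naa, th1: 15}
#' fit: {variable: E, model: gauss2, binwidth: 0.03}
#' bva: {enabled: false, n: 7}
#' output: out_dir
#' }
#'
#' @param config A path to a YAML file, a YAML string, or a list.
#' @return A validated, defaulted list of class `"pipeline_config"`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- list(
    input = NULL,
    alternation = list(D_ON = NULL, A_ON = NULL),
    background = list(window_s = 30, tail_min = "auto", method = "mle"),
    search = list(m = 10, F = NULL, min_rate_cps = NULL, stream = "all",
                  and_gate = FALSE, L = NULL),
    corrections = list(gamma = 1, leakage = 0, dir_ex = 0),
    selections = list(),
    fit = list(variable = "E", model = "gauss2", binwidth = 0.03),
    bva = list(enabled = FALSE, n = 7),
    output = "phburst_out")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  # selections is an ordered, unnamed list: merge it verbatim, not by name
  sel_in <- config$selections
  config$selections <- NULL
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(sel_in)) cfg$selections <- sel_in
  for (sec in c("alternation", "background", "search", "corrections",
                "fit", "bva")) {
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0)
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  with(cfg$search, {
    if (m < 2) stop("search: m must be >= 2")
    if (!is.null(F) && !is.null(min_rate_cps))
      stop("search: give either F or min_rate_cps, not both")
    if (!is.null(F) && F <= 1) stop("search: F must be > 1")
    if (!is.null(min_rate_cps) && min_rate_cps <= 0)
      stop("search: min_rate_cps must be > 0")
  })
  if (is.null(cfg$search$F) && is.null(cfg$search$min_rate_cps))
    cfg$search$F <- 6
  if (cfg$background$window_s <= 0)
    stop("background: window_s must be > 0")
  if (!cfg$background$method %in% c("mle", "lsq"))
    stop("background: method must be mle or lsq")
  if (!identical(cfg$background$tail_min, "auto") &&
      !(is.numeric(cfg$background$tail_min) &&
          all(cfg$background$tail_min > 0)))
    stop("background: tail_min must be 'auto' or positive seconds")
  with(cfg$corrections, {
    if (gamma <= 0) stop("corrections: gamma must be > 0")
    if (leakage < 0 || leakage >= 1)
      stop("corrections: leakage must be in [0, 1)")
    if (dir_ex < 0 || dir_ex >= 1)
      stop("corrections: dir_ex must be in [0, 1)")
  })
  for (s in cfg$selections) {
    if (is.null(s$rule) ||
        !s$rule %in% c("size", "naa", "width", "ES"))
      stop("selections: each entry needs a rule in size/naa/width/ES")
  }
  if (!cfg$fit$variable %in% c("E", "S"))
    stop("fit: variable must be E or S")
  if (!cfg$fit$model %in% c("gauss1", "gauss2", "gauss3",
                            "gauss2_plateau"))
    stop("fit: unknown model ", cfg$fit$model)
  if (cfg$fit$binwidth <= 0) stop("fit: binwidth must be > 0")
  if (cfg$bva$n < 2) stop("bva: n must be >= 2")
  structure(cfg, class = "pipeline_config")
}

config_stream <- function(name) {
  switch(name,
         all = ph_sel(all = TRUE),
         DexDem = ph_sel(dex = "Dem"), DexAem = ph_sel(dex = "Aem"),
         AexDem = ph_sel(aex = "Dem"), AexAem = ph_sel(aex = "Aem"),
         Dem = ph_sel(dex = "Dem"), Aem = ph_sel(dex = "Aem"),
         DexDAem = ph_sel(dex = c("Dem", "Aem")),
         stop("unknown stream name: ", name))
}

#' Run the burst-analysis pipeline
#'
#' Executes load, alternation, background estimation, burst search,
#' corrections, selection, population fit and (optionally) burst variance
#' analysis in order, writing the numeric artifacts (background table,
#' burst tables, fit report, BVA table) as CSV/JSON files in the output
#' directory. Any stage error is re-signalled with a stage label.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @param through Last stage to run: one of `"bg"`, `"search"`,
#'   `"select"`, `"fit"`, `"bva"`, `"all"` (default).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the final `fret_data`, the fit (if
#'   reached) and the paths written.
#' @export
run_pipeline <- function(config, through = "all", quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(cfg$input)) stop("pipeline stage 'load': no input file set")
  out_dir <- cfg$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  say("loading ", cfg$input)
  d <- stage("load", read_photon_hdf5(cfg$input))
  d <- stage("alternation", {
    if (!is.null(cfg$alternation$D_ON)) {
      d$spots <- lapply(d$spots, function(sp) {
        sp$alternation <- alternation(sp$alternation$mode,
                                      period = sp$alternation$period,
                                      D_ON = cfg$alternation$D_ON,
                                      A_ON = cfg$alternation$A_ON)
        sp
      })
    }
    if (is_alternated(d)) apply_alternation(d) else d
  })
  say("estimating background")
  d <- stage("background", estimate_background(
    d, window_s = cfg$background$window_s,
    tail_min = cfg$background$tail_min, method = cfg$background$method))
  p <- file.path(out_dir, "background.csv")
  utils::write.csv(bg_table(d), p, row.names = FALSE)
  paths <- c(paths, p)
  if (through == "bg")
    return(invisible(list(data = d, paths = paths)))
  say("burst search")
  d <- stage("search", {
    if (isTRUE(cfg$search$and_gate)) {
      burst_search_and_gate(d, m = cfg$search$m, F = cfg$search$F)
    } else {
      burst_search(d, m = cfg$search$m, F = cfg$search$F,
                   min_rate_cps = cfg$search$min_rate_cps,
                   sel = config_stream(cfg$search$stream),
                   L = cfg$search$L)
    }
  })
  d <- stage("corrections", set_corrections(
    d, gamma = cfg$corrections$gamma, leakage = cfg$corrections$leakage,
    dir_ex = cfg$corrections$dir_ex))
  p <- file.path(out_dir, "bursts.csv")
  utils::write.csv(burst_table(d), p, row.names = FALSE)
  paths <- c(paths, p)
  if (through == "search")
    return(invisible(list(data = d, paths = paths)))
  say("selection (", length(cfg$selections), " rule(s))")
  d <- stage("select", {
    for (s in cfg$selections) {
      d <- select_bursts(d, rule = s$rule,
                         th1 = if (is.null(s$th1)) 0 else s$th1,
                         th2 = if (is.null(s$th2)) Inf else s$th2,
                         gamma = s$gamma,
                         add_naa = isTRUE(s$add_naa),
                         E_range = if (is.null(s$E_range)) c(0, 1)
                                   else unlist(s$E_range),
                         S_range = if (is.null(s$S_range)) c(0, 1)
                                   else unlist(s$S_range))
    }
    d
  })
  p <- file.path(out_dir, "bursts_selected.csv")
  utils::write.csv(corrected_burst_table(d), p, row.names = FALSE)
  paths <- c(paths, p)
  if (through == "select")
    return(invisible(list(data = d, paths = paths)))
  say("fitting ", cfg$fit$variable, " histogram (", cfg$fit$model, ")")
  fit <- stage("fit", {
    bc <- burst_counts(d, 1)
    vals <- if (cfg$fit$variable == "E") bc$E_pr else bc$S_raw
    keep <- !is.na(vals)
    fit_histogram(vals[keep], burst_weights(d, 1)[keep],
                  model = cfg$fit$model, binwidth = cfg$fit$binwidth)
  })
  p <- file.path(out_dir, "fit_report.json")
  writeLines(fit_report_json(fit), p)
  paths <- c(paths, p)
  bva_res <- NULL
  if (isTRUE(cfg$bva$enabled) && through %in% c("bva", "all")) {
    say("burst variance analysis (n = ", cfg$bva$n, ")")
    bva_res <- stage("bva",
                     bva_dynamic_flag(bva(d, n = cfg$bva$n, spot = 1)))
    p <- file.path(out_dir, "bva.csv")
    utils::write.csv(as.data.frame(bva_res), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(list(data = d, fit = fit, bva = bva_res, paths = paths))
}
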
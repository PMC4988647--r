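#' Burst weights
#'
#' Size-proportional burst weights for population analysis. The variance
#' of a burst's proximity ratio is inversely proportional to its size, so
#' weighting by size gives the statistically efficient estimator of a
#' population's E; other weightings are deliberately not offered.
#'
#' @param d A [fret_data()] with background and bursts.
#' @param spot Spot index.
#' @param gamma Gamma factor (default: measurement coefficient).
#' @param add_naa Include `naa` in the size (default `FALSE`).
#' @return Non-negative numeric weights, one per burst (sizes driven
#'   negative by background subtraction are clamped to 0 here, at
#'   presentation/weighting time only).
#' @export
burst_weights <- function(d, spot = 1, gamma = NULL, add_naa = FALSE) {
  bc <- burst_counts(d, spot)
  g <- if (is.null(gamma)) d$gamma else gamma
  naa0 <- ifelse(is.na(bc$naa), 0, bc$naa)
  pmax(burst_size(bc$nd, bc$na, naa0, gamma = g, add_naa = add_naa), 0)
}

#' Weighted histogram
#'
#' Histogram with per-observation weights: the mass of a bin is the sum of
#' the weights of its members. Bins are half-open `[e, e + binwidth)` and
#' anchored so that bin edges are integer multiples of `binwidth` (for E
#' data this anchors the first edge at 0).
#'
#' @param values Numeric observations.
#' @param weights Optional weights (default: all 1).
#' @param binwidth Bin width (> 0), default 0.03.
#' @param normalize If `TRUE`, rescale masses so they sum to 1.
#' @return List with `edges` (length `n_bins + 1`), `centers`, `mass`
#'   (weighted counts) and `sumw2` (per-bin sum of squared weights, the
#'   shot-noise variance of the mass).
#' @export
weighted_histogram <- function(values, weights = NULL, binwidth = 0.03,
                               normalize = FALSE) {
  if (length(values) == 0) stop("empty input")
  if (binwidth <= 0) stop("binwidth must be > 0")
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values))
  k0 <- floor(min(values) / binwidth)
  k1 <- floor(max(values) / binwidth) + 1
  edges <- (k0:k1) * binwidth
  nb <- length(edges) - 1
  bin <- pmin(floor(values / binwidth) - k0 + 1, nb)
  mass <- vapply(seq_len(nb), function(b) sum(weights[bin == b]),
                 numeric(1))
  sumw2 <- vapply(seq_len(nb), function(b) sum(weights[bin == b]^2),
                  numeric(1))
  if (normalize && sum(mass) > 0) {
    sumw2 <- sumw2 / sum(mass)^2
    mass <- mass / sum(mass)
  }
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
       mass = mass, sumw2 = sumw2, binwidth = binwidth)
}

#' Weighted Gaussian kernel density estimate
#'
#' @param values Numeric observations.
#' @param weights Optional weights (default: all 1).
#' @param bandwidth Gaussian kernel standard deviation (default 0.03
#'   E-units).
#' @param grid Evaluation grid; default 512 points spanning the data
#'   plus/minus 4 bandwidths.
#' @return List with `x` (grid) and `y` (density, integrating to 1).
#' @export
weighted_kde <- function(values, weights = NULL, bandwidth = 0.03,
                         grid = NULL) {
  if (length(values) == 0) stop("empty input")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (is.null(grid))
    grid <- seq(min(values) - 4 * bandwidth, max(values) + 4 * bandwidth,
                length.out = 512)
  w <- weights / sum(weights)
  y <- vapply(grid, function(g)
    sum(w * stats::dnorm(g, mean = values, sd = bandwidth)), numeric(1))
  list(x = grid, y = y)
}

# ---- model definitions ----------------------------------------------------

plateau_shape <- function(x, mu1, sig1, mu2, sig2) {
  # 1 between the two centers, Gaussian roll-off outside
  ifelse(x < mu1, exp(-(x - mu1)^2 / (2 * sig1^2)),
         ifelse(x > mu2, exp(-(x - mu2)^2 / (2 * sig2^2)), 1))
}

fit_models <- function(model, values, weights, total_mass) {
  wq <- function(p) weighted_quantile(values, weights, p)
  gauss_k <- function(k, centers) {
    list(
      par = stats::setNames(
        c(rbind(total_mass / k, centers, 0.05)),
        c(outer(c("A", "mu", "sigma"), seq_len(k), paste0))),
      lower = rep(c(0, -0.1, 0.005), k),
      upper = rep(c(Inf, 1.1, 0.5), k),
      fn = function(x, p) {
        y <- 0
        for (i in seq_len(k))
          y <- y + p[[paste0("A", i)]] *
            stats::dnorm(x, p[[paste0("mu", i)]], p[[paste0("sigma", i)]])
        y
      })
  }
  switch(model,
    gauss1 = gauss_k(1, wq(0.5)),
    gauss2 = gauss_k(2, wq(c(0.25, 0.75))),
    gauss3 = gauss_k(3, wq(c(0.25, 0.5, 0.75))),
    gauss2_plateau = {
      base <- gauss_k(2, wq(c(0.25, 0.75)))
      base$par <- c(base$par, Ab = 0.01 * total_mass)
      base$lower <- c(base$lower, 0)
      base$upper <- c(base$upper, Inf)
      gfn <- base$fn
      base$fn <- function(x, p) {
        gfn(x, p) + p[["Ab"]] *
          plateau_shape(x, p[["mu1"]], p[["sigma1"]],
                        p[["mu2"]], p[["sigma2"]])
      }
      base
    },
    stop("unknown model: ", model))
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

order_components <- function(par, stderr, model) {
  k <- sum(grepl("^mu", names(par)))
  if (k < 2) return(list(par = par, stderr = stderr))
  ord <- order(par[paste0("mu", seq_len(k))])
  for (pre in c("A", "mu", "sigma")) {
    nm <- paste0(pre, seq_len(k))
    par[nm] <- par[nm][ord]
    stderr[nm] <- stderr[nm][ord]
  }
  list(par = par, stderr = stderr)
}

#' Fit a model to the weighted E/S histogram
#'
#' Builds the size-weighted histogram of the burst values and fits a
#' Gaussian-peak model to the bin masses by weighted least squares
#' (Levenberg-Marquardt). Bin uncertainties are shot-noise estimates
#' `sqrt(sum of squared member weights)` (floored at the mean weight for
#' sparse bins), so the reduced chi-squared of a well-specified model is
#' approximately 1. AIC and BIC are computed from the Gaussian-residual
#' likelihood: `AIC = 2k - 2 ln L`, `BIC = k ln(n) - 2 ln L`.
#'
#' Models: `gauss1`, `gauss2`, `gauss3` (sums of Gaussian peaks, component
#' centers returned in increasing order) and `gauss2_plateau` (two
#' Gaussians bridged by a flat plateau between the centers with Gaussian
#' roll-off outside them, for populations connected by intermediate-FRET
#' bursts). Parameters per component: mass `A`, center `mu` (bounded to
#' `[-0.1, 1.1]`), width `sigma` (bounded to `[0.005, 0.5]`).
#'
#' @param values Per-burst values (E or S).
#' @param weights Optional burst weights (default: unweighted).
#' @param model Model name (default `"gauss2"`).
#' @param binwidth Histogram bin width (default 0.03).
#' @return An object of class `"fret_fit"` with methods `print()`,
#'   `summary()`, `coef()` and `predict()`; fields include `coef`,
#'   `stderr`, `redchi`, `aic`, `bic`, `n_data`, `hist`.
#' @export
fit_histogram <- function(values, weights = NULL,
                          model = c("gauss2", "gauss1", "gauss3",
                                    "gauss2_plateau"),
                          binwidth = 0.03) {
  model <- match.arg(model)
  if (is.null(weights)) weights <- rep(1, length(values))
  h <- weighted_histogram(values, weights, binwidth)
  spec <- fit_models(model, values, weights, sum(h$mass))
  k <- length(spec$par)
  if (sum(h$mass > 0) <= k)
    stop("not enough occupied histogram bins (", sum(h$mass > 0),
         ") for a ", k, "-parameter model")
  wbar <- mean(weights)
  sigma_bin <- sqrt(pmax(h$sumw2, wbar^2))
  resid_fn <- function(p) {
    p <- as.list(stats::setNames(p, names(spec$par)))
    (h$mass - binwidth * spec$fn(h$centers, p)) / sigma_bin
  }
  res <- minpack.lm::nls.lm(
    par = spec$par, lower = spec$lower, upper = spec$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (res$info == 0 || res$info == 5)
    stop("histogram fit did not converge: ", res$message,
         " (last parameters: ",
         paste(signif(unlist(res$par), 4), collapse = ", "), ")")
  par <- unlist(res$par)
  stderr <- tryCatch({
    covm <- res$deviance / (length(h$mass) - k) *
      solve(res$hessian)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, k))
  names(stderr) <- names(par)
  oc <- order_components(par, stderr, model)
  n <- length(h$mass)
  rss <- res$deviance          # sum of (scaled) squared residuals
  loglik <- -0.5 * rss - 0.5 * sum(log(2 * pi * sigma_bin^2))
  structure(list(method = "histogram", model = model, coef = oc$par,
                 stderr = oc$stderr, redchi = rss / (n - k),
                 aic = 2 * k - 2 * loglik,
                 bic = k * log(n) - 2 * loglik,
                 loglik = loglik, n_data = n, n_par = k, hist = h,
                 binwidth = binwidth, model_fn = spec$fn),
            class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<fret_fit> %s fit, model %s\n", x$method, x$model))
  tab <- data.frame(value = signif(x$coef, digits),
                    stderr = signif(x$stderr, digits))
  print(tab)
  if (!is.na(x$redchi))
    cat(sprintf("  reduced chi2 %.3f  ", x$redchi))
  cat(sprintf("AIC %.1f  BIC %.1f  (n = %d)\n", x$aic, x$bic, x$n_data))
  invisible(x)
}

#' @export
coef.fret_fit <- function(object, ...) object$coef

#' @export
summary.fret_fit <- function(object, ...) {
  out <- list(model = object$model, method = object$method,
              coefficients = cbind(Estimate = object$coef,
                                   `Std. Error` = object$stderr),
              redchi = object$redchi, aic = object$aic, bic = object$bic,
              n_data = object$n_data)
  class(out) <- "summary.fret_fit"
  out
}

#' @export
print.summary.fret_fit <- function(x, ...) {
  cat(sprintf("Model: %s (%s fit)\n", x$model, x$method))
  stats::printCoefmat(x$coefficients, na.print = "NA")
  cat(sprintf("reduced chi2: %s  AIC: %.2f  BIC: %.2f  n: %d\n",
              if (is.na(x$redchi)) "NA" else sprintf("%.3f", x$redchi),
              x$aic, x$bic, x$n_data))
  invisible(x)
}

#' @export
predict.fret_fit <- function(object, newdata = NULL, ...) {
  if (object$method != "histogram")
    stop("predict() is defined for histogram fits")
  x <- if (is.null(newdata)) object$hist$centers else newdata
  object$model_fn(x, as.list(object$coef))
}

#' @export
plot.fret_fit <- function(x, ...) {
  h <- x$hist
  graphics::plot(h$centers, h$mass, type = "h", lwd = 4, col = "grey70",
                 xlab = "value", ylab = "weighted counts", ...)
  if (x$method == "histogram") {
    xs <- seq(min(h$edges), max(h$edges), length.out = 400)
    graphics::lines(xs, x$binwidth * x$model_fn(xs, as.list(x$coef)),
                    col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Machine-readable fit report
#'
#' @param fit A `"fret_fit"` object.
#' @return JSON string with values, standard errors, reduced chi-squared,
#'   AIC and BIC.
#' @export
fit_report_json <- function(fit) {
  jsonlite::toJSON(list(model = fit$model, method = fit$method,
                        values = as.list(fit$coef),
                        stderr = as.list(fit$stderr),
                        redchi = fit$redchi, aic = fit$aic, bic = fit$bic,
                        n_data = fit$n_data),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

# ---- weighted EM ----------------------------------------------------------

em_loglik <- function(values, weights, mu, sigma, pi_k) {
  dens <- vapply(seq_along(mu), function(j)
    pi_k[j] * stats::dnorm(values, mu[j], sigma[j]),
    numeric(length(values)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(values))
  sum(weights * log(pmax(rowSums(dens), 1e-300)))
}

em_run <- function(values, weights, mu, sigma, pi_k, tol, max_iter) {
  k <- length(mu)
  ll_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      pi_k[j] * stats::dnorm(values, mu[j], sigma[j]),
      numeric(length(values)))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(values))
    tot <- pmax(rowSums(dens), 1e-300)
    resp <- dens / tot
    wresp <- resp * weights
    nk <- colSums(wresp)
    pi_k <- nk / sum(weights)
    mu <- colSums(wresp * values) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j)
      sum(wresp[, j] * (values - mu[j])^2) / nk[j], numeric(1)))
    if (any(sigma < 1e-4)) return(list(collapsed = TRUE))
    ll <- sum(weights * log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) <=
        tol * abs(ll_prev)) {
      return(list(collapsed = FALSE, mu = mu, sigma = sigma, pi_k = pi_k,
                  loglik = ll, trace = trace, n_iter = it,
                  converged = TRUE))
    }
    ll_prev <- ll
  }
  list(collapsed = FALSE, mu = mu, sigma = sigma, pi_k = pi_k,
       loglik = ll_prev, trace = trace, n_iter = max_iter,
       converged = FALSE)
}

em_hessian_se <- function(values, weights, mu, sigma, pi_k) {
  k <- length(mu)
  theta <- c(mu, sigma, if (k > 1) pi_k[-k])
  f <- function(th) {
    m <- th[1:k]; s <- th[(k + 1):(2 * k)]
    p <- if (k > 1) c(th[(2 * k + 1):(3 * k - 1)],
                      1 - sum(th[(2 * k + 1):(3 * k - 1)])) else 1
    if (any(s <= 0) || any(p <= 0)) return(-Inf)
    em_loglik(values, weights, m, s, p)
  }
  np <- length(theta)
  eps <- pmax(abs(theta), 0.05) * 1e-4
  H <- matrix(NA_real_, np, np)
  f0 <- f(theta)
  for (i in seq_len(np)) for (j in i:np) {
    ei <- ej <- rep(0, np); ei[i] <- eps[i]; ej[j] <- eps[j]
    H[i, j] <- H[j, i] <-
      (f(theta + ei + ej) - f(theta + ei - ej) -
         f(theta - ei + ej) + f(theta - ei - ej)) / (4 * eps[i] * eps[j])
  }
  se <- tryCatch(sqrt(pmax(diag(solve(-H)), 0)),
                 error = function(e) rep(NA_real_, np))
  list(mu = se[1:k], sigma = se[(k + 1):(2 * k)],
       pi = if (k > 1) c(se[(2 * k + 1):(3 * k - 1)], NA_real_) else
         NA_real_)
}

#' Weighted expectation-maximization Gaussian mixture fit
#'
#' Fits a k-component Gaussian mixture to per-burst values with burst
#' weights acting as case multiplicities. Initialization is deterministic
#' (component centers at weighted quantiles); the weighted log-likelihood
#' is non-decreasing across iterations and convergence is declared at a
#' relative change below `tol`. A component collapsing to `sigma < 1e-4`
#' triggers one restart from a perturbed initialization, then an error.
#'
#' @param values Per-burst values (E or S).
#' @param weights Optional weights (default: unweighted).
#' @param k Number of components (1-3).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `c("fret_em", "fret_fit")`: `coef` holds the
#'   interleaved `mu`, `sigma` and mixture `fraction` of each component
#'   (centers in increasing order), `stderr` their asymptotic standard
#'   errors from the observed information, plus `loglik`, `aic`, `bic`,
#'   `n_iter`, `loglik_trace`.
#' @export
fit_em_gaussian <- function(values, weights = NULL, k = 2, tol = 1e-8,
                            max_iter = 500) {
  if (!(k %in% 1:3)) stop("k must be 1, 2 or 3")
  if (length(values) <= 10 * k)
    stop("need more than ", 10 * k, " values for k = ", k)
  if (is.null(weights)) weights <- rep(1, length(values))
  mu0 <- weighted_quantile(values, weights, (1:k) / (k + 1))
  wm <- sum(weights * values) / sum(weights)
  s0 <- rep(max(sqrt(sum(weights * (values - wm)^2) / sum(weights)) /
                  max(1, k), 0.02), k)
  res <- em_run(values, weights, mu0, s0, rep(1 / k, k), tol, max_iter)
  if (isTRUE(res$collapsed)) {
    res <- em_run(values, weights,
                  mu0 + 0.05 * rep_len(c(-1, 1, 0), k), s0 * 2,
                  rep(1 / k, k), tol, max_iter)
    if (isTRUE(res$collapsed))
      stop("EM component collapse (sigma < 1e-4) after restart")
  }
  ord <- order(res$mu)
  mu <- res$mu[ord]; sigma <- res$sigma[ord]; pi_k <- res$pi_k[ord]
  se <- em_hessian_se(values, weights, mu, sigma, pi_k)
  cf <- stats::setNames(
    c(rbind(mu, sigma, pi_k)),
    c(outer(c("mu", "sigma", "fraction"), seq_len(k), paste0)))
  sev <- stats::setNames(
    c(rbind(se$mu, se$sigma, se$pi)), names(cf))
  n_par <- 3 * k - 1
  structure(list(method = "em", model = paste0("gaussmix", k), coef = cf,
                 stderr = sev, redchi = NA_real_, loglik = res$loglik,
                 aic = 2 * n_par - 2 * res$loglik,
                 bic = n_par * log(length(values)) - 2 * res$loglik,
                 n_data = length(values), n_par = n_par,
                 n_iter = res$n_iter, converged = res$converged,
                 loglik_trace = res$trace,
                 hist = weighted_histogram(values, weights)),
            class = c("fret_em", "fret_fit"))
}
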
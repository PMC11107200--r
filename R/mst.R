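#' Construct a thermophoresis trace
#'
#' @param time strictly increasing times (s); by convention the infrared
#'   laser switches on at t = 0.
#' @param fluorescence fluorescence counts, same length.
#' @param concentration ligand concentration (molar, >= 0).
#' @return Object of class \code{mst_trace}.
#' @export
mst_trace <- function(time, fluorescence, concentration) {
  if (length(time) != length(fluorescence))
    stop("time and fluorescence differ in length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (concentration < 0) stop("concentration must be non-negative")
  out <- list(time = as.numeric(time),
              fluorescence = as.numeric(fluorescence),
              concentration = concentration)
  class(out) <- "mst_trace"
  out
}

#' Normalised fluorescence of a thermophoresis trace
#'
#' Fnorm = 1000 x mean fluorescence in the hot window divided by the mean
#' in the cold window, in per-mil; the hot/cold difference across a
#' dilution series is the thermophoresis binding signal.
#'
#' @param trace an [mst_trace()].
#' @param cold_window,hot_window length-2 time intervals (s) within the
#'   trace support, non-overlapping; defaults follow the usual convention
#'   of a pre-laser cold window and a late hot window.
#' @return Fnorm in per-mil.
#' @export
fnorm <- function(trace, cold_window = c(-1, 0), hot_window = c(19, 20)) {
  rng <- range(trace$time)
  for (w in list(cold_window, hot_window))
    if (w[1] < rng[1] || w[2] > rng[2])
      stop("window outside the trace's time support")
  if (max(cold_window[1], hot_window[1]) < min(cold_window[2], hot_window[2]))
    stop("cold and hot windows overlap")
  mean_in <- function(w)
    mean(trace$fluorescence[trace$time >= w[1] & trace$time <= w[2]])
  cold <- mean_in(cold_window)
  if (!is.finite(cold) || cold <= 0)
    stop("non-positive cold-window fluorescence")
  1000 * mean_in(hot_window) / cold
}

# Bound fraction under the 1:1 probe-depletion (quadratic) isotherm.
.bound_fraction <- function(L, P, Kd) {
  s <- P + L + Kd
  (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
}

#' Fit a 1:1 binding isotherm to an MST dilution series
#'
#' Fits delta-Fnorm against ligand concentration with the quadratic
#' probe-depletion model: response = baseline + amplitude x bound
#' fraction, where the bound fraction of a probe at concentration P with
#' ligand L and dissociation constant Kd is
#' ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P).  Nonlinear
#' least squares with five log-spaced Kd starts; when the fitted Kd does
#' not exceed the probe concentration the experiment cannot resolve a
#' smaller Kd and the estimate is flagged as a lower limit.
#'
#' @param concentrations ligand concentrations (molar), at least 6 values
#'   spanning at least 3 orders of magnitude.
#' @param delta_fnorm thermophoresis responses (per-mil), same length.
#' @param probe_conc labelled-probe concentration (molar).
#' @param n_starts number of log-spaced Kd initialisations.
#' @return An object of class \code{kd_fit} with components \code{kd},
#'   \code{amplitude}, \code{baseline}, \code{kd_is_lower_limit},
#'   \code{probe_conc}, \code{fitted}, \code{residuals}, \code{data} and
#'   \code{sigma}.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{plot},
#'   \code{simulate}.
#' @export
fit_kd <- function(concentrations, delta_fnorm, probe_conc, n_starts = 5) {
  L <- as.numeric(concentrations); y <- as.numeric(delta_fnorm)
  if (length(L) != length(y)) stop("lengths differ")
  ord <- order(L); L <- L[ord]; y <- y[ord]
  if (length(L) < 6) stop("need at least 6 concentrations")
  pos <- L[L > 0]
  if (log10(max(pos) / min(pos)) < 3)
    stop("concentrations must span at least 3 orders of magnitude")
  if (probe_conc <= 0) stop("probe concentration must be positive")

  if (diff(range(y)) < sqrt(.Machine$double.eps) * max(1, abs(mean(y))))
    stop("no binding detected: amplitude indistinguishable from noise")
  starts <- 10^seq(log10(min(pos) / 10), log10(max(pos) * 10),
                   length.out = n_starts)
  dat <- data.frame(L = L, y = y)
  slope <- unname(coef(stats::lm(y ~ log10(L + min(pos))))[2])
  a0 <- diff(range(y)) * if (is.finite(slope) && slope != 0)
    sign(slope) else -1
  best <- NULL; best_dev <- Inf
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * .bound_fraction(L, probe_conc, exp(lk)),
        data = dat,
        start = list(b = min(y), a = a0, lk = log(k0)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dv <- sum(resid(fit)^2)
      if (dv < best_dev) { best <- fit; best_dev <- dv }
    }
  }
  if (is.null(best)) stop("isotherm fit failed from every start")
  cf <- coef(best)
  kd <- exp(cf[["lk"]]); amp <- cf[["a"]]; base <- cf[["b"]]
  res <- as.numeric(resid(best))
  sigma <- sqrt(sum(res^2) / max(1, length(y) - 3))
  if (abs(amp) < 3 * sigma ||
      abs(amp) < sqrt(.Machine$double.eps) * max(1, abs(base)))
    stop("no binding detected: amplitude indistinguishable from noise")
  out <- list(kd = kd, amplitude = amp, baseline = base,
              kd_is_lower_limit = kd <= probe_conc,
              probe_conc = probe_conc,
              fitted = as.numeric(stats::fitted(best)),
              residuals = res, sigma = sigma,
              data = dat, nls = best, call = match.call())
  class(out) <- "kd_fit"
  out
}

#' @export
print.kd_fit <- function(x, ...) {
  unit <- if (x$kd < 1e-6) c(1e9, "nM") else c(1e6, "uM")
  cat(sprintf("1:1 probe-depletion binding fit: Kd = %.3g %s%s\n",
              x$kd * as.numeric(unit[1]), unit[2],
              if (x$kd_is_lower_limit)
                " (lower limit: probe concentration >= Kd)" else ""))
  cat(sprintf("  amplitude %.3g, baseline %.3g (per-mil), residual sd %.3g\n",
              x$amplitude, x$baseline, x$sigma))
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  s <- summary(object$nls)
  cat(sprintf("Kd: %.4g M (probe %.4g M)%s\n", object$kd, object$probe_conc,
              if (object$kd_is_lower_limit) " -- LOWER LIMIT" else ""))
  cat(sprintf("n = %d concentrations, residual sd %.4g per-mil\n",
              nrow(object$data), object$sigma))
  print(s$coefficients)
  invisible(s)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, amplitude = object$amplitude, baseline = object$baseline)
}

#' @export
fitted.kd_fit <- function(object, ...) object$fitted

#' @export
residuals.kd_fit <- function(object, ...) object$residuals

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else
    if (is.list(newdata)) newdata$L else as.numeric(newdata)
  object$baseline + object$amplitude *
    .bound_fraction(L, object$probe_conc, object$kd)
}

#' @export
plot.kd_fit <- function(x, ...) {
  L <- x$data$L
  graphics::plot(L, x$data$y, log = "x", xlab = "ligand (M)",
                 ylab = expression(Delta * F[norm] ~ "(per-mil)"), ...)
  Lg <- 10^seq(log10(min(L[L > 0])), log10(max(L)), length.out = 200)
  graphics::lines(Lg, predict(x, Lg))
  graphics::abline(v = x$kd, lty = 2)
  invisible(x)
}

#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- replicate(nsim, mu + rnorm(length(mu), 0, object$sigma),
                   simplify = FALSE)
  data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Build a binding curve from raw MST traces
#'
#' Computes Fnorm for each capillary trace and fits the 1:1 isotherm.
#'
#' @param traces list of [mst_trace()] objects.
#' @param probe_conc labelled-probe concentration (molar).
#' @param cold_window,hot_window passed to [fnorm()].
#' @return A \code{kd_fit}; the per-capillary Fnorm values are in
#'   \code{$data}.
#' @export
binding_curve <- function(traces, probe_conc, cold_window = c(-1, 0),
                          hot_window = c(19, 20)) {
  conc <- vapply(traces, function(tr) tr$concentration, numeric(1))
  fn <- vapply(traces, fnorm, numeric(1),
               cold_window = cold_window, hot_window = hot_window)
  fit_kd(conc, fn, probe_conc)
}
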
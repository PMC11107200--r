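#' Construct an absorbance spectrum
#'
#' @param wavelength strictly increasing wavelengths (nm).
#' @param absorbance absorbance values (AU), same length, finite.
#' @param label optional label.
#' @return Object of class \code{spectrum}.
#' @export
spectrum <- function(wavelength, absorbance, label = "") {
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance differ in length")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  out <- list(wavelength = as.numeric(wavelength),
              absorbance = as.numeric(absorbance), label = label)
  class(out) <- "spectrum"
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s'> %d points, %.0f-%.0f nm, max A %.3g\n",
              x$label, length(x$wavelength), min(x$wavelength),
              max(x$wavelength), max(x$absorbance)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$absorbance, type = "l",
                 xlab = "wavelength (nm)", ylab = "absorbance (AU)",
                 main = x$label, ...)
  invisible(x)
}

#' Read a two-column wavelength/absorbance CSV
#'
#' @param path CSV file with columns wavelength_nm, absorbance (header
#'   optional).
#' @param label spectrum label; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  d <- utils::read.csv(path, header = has_header)
  spectrum(d[[1]], d[[2]], label = label)
}

#' Area-normalise a spectrum
#'
#' Rescales so that the trapezoidal integral of |absorbance| over
#' \code{range} equals 1, enabling comparison of spectra recorded with
#' different extinction coefficients and path lengths (e.g. solution vs
#' single-crystal data).
#'
#' @param s a [spectrum()].
#' @param range length-2 nm interval within the spectrum's support
#'   (default: full support).
#' @return The normalised [spectrum()].
#' @export
area_normalize <- function(s, range = NULL) {
  if (is.null(range)) range <- range(s$wavelength)
  if (range[1] < min(s$wavelength) || range[2] > max(s$wavelength))
    stop("normalization range outside the spectrum's support")
  keep <- s$wavelength >= range[1] & s$wavelength <= range[2]
  w <- s$wavelength[keep]; a <- abs(s$absorbance[keep])
  # include interpolated endpoints so the integral covers the exact range
  for (edge in range) {
    if (!any(w == edge)) {
      a <- c(a, abs(approx(s$wavelength, s$absorbance, xout = edge)$y))
      w <- c(w, edge)
    }
  }
  o <- order(w)
  area <- pracma::trapz(w[o], a[o])
  if (area <= 1e-12) stop("zero-area spectrum cannot be normalized")
  spectrum(s$wavelength, s$absorbance / area, label = s$label)
}

#' Band positions and heights of a cobalamin spectrum
#'
#' Reports, on the area-normalised spectrum, the argmax wavelength and
#' height inside the gamma window and the alpha/beta window.  These are
#' the diagnostic cobalamin bands: collapse of the gamma band and a red
#' shift of the alpha/beta band signal replacement of the beta-axial
#' ligand (e.g. hydroxo by glutathionyl).
#'
#' @param s a [spectrum()].
#' @param gamma_window,alphabeta_window length-2 nm intervals within the
#'   support.
#' @param normalize area-normalise first (default \code{TRUE}).
#' @return List with \code{gamma} and \code{alphabeta}, each holding
#'   \code{position} (nm) and \code{height}.
#' @export
band_metrics <- function(s, gamma_window = c(340, 370),
                         alphabeta_window = c(490, 580), normalize = TRUE) {
  if (normalize) s <- area_normalize(s)
  pick <- function(win) {
    if (win[1] < min(s$wavelength) || win[2] > max(s$wavelength))
      stop("band window outside the spectrum's support")
    keep <- s$wavelength >= win[1] & s$wavelength <= win[2]
    w <- s$wavelength[keep]; a <- s$absorbance[keep]
    if (diff(range(a)) < 1e-12) {
      warning("flat band window; reporting its midpoint")
      return(list(position = mean(win), height = a[1]))
    }
    i <- which.max(a)
    list(position = w[i], height = a[i])
  }
  list(gamma = pick(gamma_window), alphabeta = pick(alphabeta_window))
}

#' Compare two spectra by band shift and gamma collapse
#'
#' @param a reference [spectrum()] (e.g. hydroxocobalamin-like).
#' @param b comparison [spectrum()] (e.g. glutathionylcobalamin-like).
#' @param gamma_window,alphabeta_window band windows (nm).
#' @return List with \code{red_shift_nm} (alpha/beta band position of b
#'   minus a) and \code{gamma_ratio} (gamma height of b over a, after
#'   area normalisation).
#' @export
compare_spectra <- function(a, b, gamma_window = c(340, 370),
                            alphabeta_window = c(490, 580)) {
  ma <- band_metrics(a, gamma_window, alphabeta_window)
  mb <- band_metrics(b, gamma_window, alphabeta_window)
  list(red_shift_nm = mb$alphabeta$position - ma$alphabeta$position,
       gamma_ratio = mb$gamma$height / ma$gamma$height)
}

#' Spectral drift over a time course
#'
#' Quantifies the stability of a chromophore by the L2 distance between
#' each timepoint's area-normalised spectrum and the area-normalised
#' reference, on a common 1 nm linear-interpolation grid, together with
#' the Kendall rank correlation of drift against time (a monotone-decay
#' statistic: near 0 for a stable series, near 1 for steady conversion).
#'
#' @param reference a [spectrum()].
#' @param times numeric timepoints (>= 2).
#' @param series list of [spectrum()] objects, same length as
#'   \code{times}, sharing a common wavelength range with the reference.
#' @return List with \code{drift} (data frame time/drift) and \code{tau}.
#' @export
stability_series <- function(reference, times, series) {
  if (length(series) < 2 || length(times) != length(series))
    stop("need at least 2 timepoints with one spectrum each")
  lo <- max(vapply(c(list(reference), series),
                   function(s) min(s$wavelength), numeric(1)))
  hi <- min(vapply(c(list(reference), series),
                   function(s) max(s$wavelength), numeric(1)))
  if (hi <= lo) stop("spectra share no common wavelength range")
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  regrid <- function(s) {
    s <- area_normalize(s, c(grid[1], grid[length(grid)]))
    approx(s$wavelength, s$absorbance, xout = grid)$y
  }
  ref <- regrid(reference)
  drift <- vapply(series, function(s) {
    d <- regrid(s) - ref
    sqrt(pracma::trapz(grid, d^2))
  }, numeric(1))
  # a perfectly stable series has no trend by convention
  tau <- if (diff(range(drift)) < 1e-12) 0 else
    suppressWarnings(cor(times, drift, method = "kendall"))
  list(drift = data.frame(time = times, drift = drift), tau = tau)
}
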
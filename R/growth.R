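#' Exponential growth rate from an optical-density time series
#'
#' Ordinary least-squares fit of `ln(OD)` versus time, restricted to the
#' points whose OD lies in the fitting window (default 0.1-0.3, the range in
#' which photobioreactor OD readings track exponential growth linearly).
#' Window membership is a closed interval.
#'
#' @param time Time in hours, strictly increasing.
#' @param od Optical density (720 or 730 nm), positive.
#' @param window Two-element OD window `c(lo, hi)`.
#' @return Growth rate mu in h-1 (slope of the log-linear fit).
#' @examples
#' t <- 0:40
#' fit_growth_rate(t, 0.05 * exp(0.06 * t))  # 0.06
#' @export
fit_growth_rate <- function(time, od, window = c(0.1, 0.3)) {
  stopifnot(length(time) == length(od), !is.unsorted(time, strictly = TRUE))
  if (any(od <= 0)) stop("od must be positive")
  keep <- od >= window[1] & od <= window[2]
  if (sum(keep) < 3)
    stop("need at least 3 points with OD inside the fitting window")
  stats::coef(stats::lm(log(od[keep]) ~ time[keep]))[[2]]
}

#' Generation (doubling) time from a growth rate
#'
#' @param mu Specific growth rate, h-1 (> 0).
#' @return Generation time `ln(2) / mu` in hours.
#' @examples
#' generation_time(0.058)  # ~12 h, the 4% CO2 library culture
#' @export
generation_time <- function(mu) {
  if (any(mu <= 0)) stop("mu must be positive")
  log(2) / mu
}

#' Scatter-correct and normalize a whole-cell absorption spectrum
#'
#' Whole-cell spectra carry a broad light-scatter baseline. The correction
#' normalizes the spectrum to unit absorbance at 730 nm and subtracts the
#' chord through the (560 nm, 730 nm) points, which approximates the scatter
#' contribution across the pigment absorption region. The corrected spectrum
#' is therefore zero at both 560 and 730 nm.
#'
#' @param wavelength Wavelengths in nm, increasing; must cover 560-730 nm.
#' @param absorbance Absorbance values (OD units).
#' @param extrapolate If TRUE (default) the chord is extended linearly outside
#'   560-730 nm; if FALSE the correction is applied only inside the range.
#' @return data.frame with `wavelength` and corrected `absorbance`.
#' @export
correct_spectrum_scatter <- function(wavelength, absorbance,
                                     extrapolate = TRUE) {
  stopifnot(length(wavelength) == length(absorbance),
            !is.unsorted(wavelength))
  if (min(wavelength) > 560 || max(wavelength) < 730)
    stop("spectrum must cover 560-730 nm for scatter correction")
  a730 <- stats::approx(wavelength, absorbance, xout = 730)$y
  if (!is.finite(a730) || a730 == 0) stop("absorbance at 730 nm must be nonzero")
  norm <- absorbance / a730
  a560 <- stats::approx(wavelength, norm, xout = 560)$y
  slope <- (1 - a560) / (730 - 560)
  chord <- a560 + slope * (wavelength - 560)
  corrected <- norm - chord
  if (!extrapolate) {
    outside <- wavelength < 560 | wavelength > 730
    corrected[outside] <- norm[outside]
  }
  data.frame(wavelength = wavelength, absorbance = corrected)
}
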
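# Ellman-assay inhibition math, four-parameter logistic IC50 estimation,
# and the Scherrer crystallite-size utility.

#' Percent enzyme inhibition (Ellman method)
#'
#' \code{(1 - A_sample / A_control) * 100}: 0 when the sample absorbance
#' equals the uninhibited control, 100 at complete inhibition.
#'
#' @param abs_sample sample absorbance(s), non-negative.
#' @param abs_control control absorbance, strictly positive.
#' @return percent inhibition (vectorized over \code{abs_sample}).
#' @export
percent_inhibition <- function(abs_sample, abs_control) {
  if (!is.finite(abs_control) || abs_control <= 0)
    stop("control absorbance must be positive, got ", abs_control)
  if (any(abs_sample < 0)) stop("sample absorbance must be non-negative")
  (1 - abs_sample / abs_control) * 100
}

#' Construct a dose-response record
#'
#' @param concentrations strictly positive doses (ug/mL).
#' @param inhibition_pct percent inhibition at each dose.
#' @param replicate_id optional label.
#' @return list of class \code{dose_response}, sorted by concentration.
#' @export
dose_response <- function(concentrations, inhibition_pct, replicate_id = NA) {
  if (length(concentrations) != length(inhibition_pct))
    stop("concentrations and inhibition_pct differ in length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be strictly positive and finite")
  ord <- order(concentrations)
  conc <- concentrations[ord]
  if (any(diff(conc) <= 0)) stop("concentrations must be distinct")
  structure(list(concentrations = conc, inhibition_pct = inhibition_pct[ord],
                 replicate_id = replicate_id), class = "dose_response")
}

#' Four-parameter logistic model
#'
#' \code{y = bottom + (top - bottom) / (1 + (ic50 / x)^hill)}; increasing in
#' dose for positive hill slopes, with y = (top+bottom)/2 at x = ic50.
#'
#' @param x doses.
#' @param bottom,top lower/upper plateaus (percent).
#' @param ic50 half-maximal dose.
#' @param hill slope.
#' @export
logistic4 <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / x)^hill)
}

#' Fit a four-parameter logistic and report the IC50
#'
#' Levenberg-Marquardt least squares (\code{minpack.lm::nlsLM}).
#' Initialization: bottom = min(y), top = max(y), ic50 = geometric median
#' dose, hill = 1. Non-convergence is reported honestly via
#' \code{converged = FALSE} with the solver message, never as a silent fit.
#'
#' @param dr a \code{dose_response} with at least 4 distinct doses.
#' @return list of class \code{ic50_fit}: ic50, hill, top, bottom, rss,
#'   converged, method, message.
#' @export
fit_ic50 <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  x <- dr$concentrations
  y <- dr$inhibition_pct
  if (length(unique(x)) < 4L)
    stop("IC50 fit needs >= 4 distinct concentrations spanning the transition, got ",
         length(unique(x)))
  start <- list(bottom = min(y), top = max(y),
                ic50 = exp(stats::median(log(x))), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ logistic4(x, bottom, top, ic50, hill),
      start = start,
      lower = c(bottom = -Inf, top = -Inf, ic50 = .Machine$double.eps, hill = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_, converged = FALSE,
                          method = "4PL-LM", message = conditionMessage(fit)),
                     class = "ic50_fit"))
  }
  p <- as.list(stats::coef(fit))
  structure(list(ic50 = p$ic50, hill = p$hill, top = p$top, bottom = p$bottom,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, method = "4PL-LM",
                 message = fit$convInfo$stopMessage),
            class = "ic50_fit")
}

#' Scherrer crystallite size from X-ray peak broadening
#'
#' D = k * lambda / (beta * cos(theta)), converted from Angstrom to nm.
#'
#' @param fwhm_rad peak full width at half maximum (radians), positive.
#' @param theta_rad Bragg angle theta (radians), in (0, pi/2).
#' @param wavelength X-ray wavelength in Angstrom (Cu K-alpha 1.5406 by
#'   default).
#' @param k dimensionless shape factor (0.9 for near-spherical crystallites).
#' @return crystallite size in nm.
#' @export
scherrer_size <- function(fwhm_rad, theta_rad, wavelength = 1.5406, k = 0.9) {
  if (!is.finite(fwhm_rad) || fwhm_rad <= 0)
    stop("FWHM must be positive, got ", fwhm_rad)
  if (!is.finite(theta_rad) || theta_rad <= 0 || theta_rad >= pi / 2)
    stop("theta must lie in (0, pi/2) radians, got ", theta_rad)
  (k * wavelength / (fwhm_rad * cos(theta_rad))) / 10  # Angstrom -> nm
}
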
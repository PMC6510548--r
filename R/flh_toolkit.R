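# Hyperspectral fluorescence line height: quadratic baseline through anchor
# bands and line height at a retrieval band.

#' FLH band configuration
#'
#' @param anchors anchor-band wavelengths [nm] (>= 3 for a quadratic
#'   baseline); defaults 640, 710, 745
#' @param retrieval retrieval band [nm], inside the anchor span; default 680
#' @param order baseline polynomial order (2)
#' @return object of class `flh_config`
#' @export
flh_config <- function(anchors = c(640, 710, 745), retrieval = 680,
                       order = 2) {
  anchors <- sort(anchors)
  if (length(anchors) < order + 1) {
    stop("need at least order + 1 anchor bands")
  }
  if (retrieval < min(anchors) || retrieval > max(anchors)) {
    stop("retrieval band must lie inside the anchor span")
  }
  structure(list(anchors = anchors, retrieval = retrieval, order = order),
            class = "flh_config")
}

# anchor reflectances read from the (typically ILS-convolved) spectrum by
# linear interpolation, mimicking a band-sampling sensor
anchor_values <- function(wavelength, reflectance, config) {
  if (min(config$anchors) < min(wavelength) ||
      max(config$anchors) > max(wavelength)) {
    stop("anchor bands outside the spectrum")
  }
  stats::approx(wavelength, reflectance, config$anchors)$y
}

#' Fit the fluorescence-free baseline
#'
#' Quadratic (or order-`order`) polynomial through the anchor-band
#' reflectances: exact interpolation when the number of anchors equals
#' order + 1, least squares otherwise. Coefficients are in powers of
#' (lambda - retrieval band) for conditioning.
#'
#' @param wavelength spectrum wavelengths [nm]
#' @param reflectance spectrum values
#' @param config an [flh_config()]
#' @return list with `coef` (ascending powers), `center`, and the anchor
#'   values used
#' @export
fit_baseline <- function(wavelength, reflectance, config = flh_config()) {
  y <- anchor_values(wavelength, reflectance, config)
  x <- config$anchors - config$retrieval
  X <- outer(x, 0:config$order, `^`)
  cf <- if (length(y) == config$order + 1) {
    solve(X, y)
  } else {
    stats::lsfit(X, y, intercept = FALSE)$coefficients
  }
  list(coef = unname(cf), center = config$retrieval, anchors = y)
}

#' Evaluate a fitted baseline
#'
#' @param baseline result of [fit_baseline()]
#' @param wavelength wavelengths [nm]
#' @return baseline values
#' @export
baseline_value <- function(baseline, wavelength) {
  x <- wavelength - baseline$center
  as.vector(outer(x, seq_along(baseline$coef) - 1, `^`) %*% baseline$coef)
}

#' Fluorescence line height
#'
#' Reflectance at the retrieval band minus the fitted baseline there.
#' Negative values are retained as a diagnostic.
#'
#' @inheritParams fit_baseline
#' @return line height in the units of the spectrum
#' @export
flh <- function(wavelength, reflectance, config = flh_config()) {
  bl <- fit_baseline(wavelength, reflectance, config)
  obs <- stats::approx(wavelength, reflectance, config$retrieval)$y
  obs - baseline_value(bl, config$retrieval)
}
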
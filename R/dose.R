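#' Default exposure dose model
#'
#' The cellular-print calibration used on the instrument: 200 um layers
#' crosslink in 60 s and 300 um layers in 120 s, both at 10 mW/cm^2.
#' Queries at other thicknesses interpolate linearly between tabulated
#' points (clamped to the end values outside the table, with a warning);
#' queries at other irradiances apply constant-dose scaling.
#'
#' @param interpolate allow linear interpolation in thickness?
#' @return a [DoseModel-class].
#' @export
defaultDoseModel <- function(interpolate = TRUE) {
  DoseModel(thickness = c(200, 300), time = c(60, 120),
            referenceIntensity = 10, interpolate = interpolate)
}

#' @describeIn DoseModel Constructor.
#' @param thickness,time,referenceIntensity,interpolate see slots.
#' @export
DoseModel <- function(thickness, time, referenceIntensity = 10,
                      interpolate = TRUE) {
  o <- order(thickness)
  new("DoseModel", thickness = as.numeric(thickness)[o],
      time = as.numeric(time)[o],
      referenceIntensity = as.numeric(referenceIntensity),
      interpolate = isTRUE(interpolate))
}

#' Exposure time for a layer
#'
#' Returns the crosslinking time for a layer of the given thickness at the
#' given irradiance, assuming a constant required dose: the tabulated time
#' at the reference irradiance is scaled by `referenceIntensity /
#' intensity`.
#'
#' @param thickness layer thickness (um).
#' @param intensity irradiance at the build plane (mW/cm^2).
#' @param model a [DoseModel-class]; default [defaultDoseModel()].
#' @return exposure time in seconds.
#' @examples
#' exposureTime(200, 10)  # 60 s
#' exposureTime(300, 10)  # 120 s
#' exposureTime(200, 20)  # 30 s: double the irradiance, half the time
#' @export
exposureTime <- function(thickness, intensity, model = defaultDoseModel()) {
  if (intensity <= 0) stop("intensity must be > 0")
  hit <- match(thickness, model@thickness)
  if (!is.na(hit)) {
    t0 <- model@time[hit]
  } else if (model@interpolate) {
    if (thickness < model@thickness[1] ||
        thickness > model@thickness[length(model@thickness)]) {
      warning(sprintf(
        "thickness %.0f um outside the calibrated range [%g, %g]; clamped",
        thickness, model@thickness[1],
        model@thickness[length(model@thickness)]))
      t0 <- if (thickness < model@thickness[1]) model@time[1]
            else model@time[length(model@time)]
    } else {
      t0 <- stats::approx(model@thickness, model@time, xout = thickness)$y
    }
  } else {
    stop(sprintf(
      "no dose entry for thickness %g um (known: %s) and interpolation is off",
      thickness, paste(model@thickness, collapse = ", ")))
  }
  t0 * model@referenceIntensity / intensity
}
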
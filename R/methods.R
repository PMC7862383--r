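#' @describeIn MaskStack-class list of the stack's `Mask` objects.
#' @export
setMethod("masks", "MaskStack", function(x) x@masks)

#' @describeIn PrintSchedule-class the ordered event data.frame.
#' @export
setMethod("events", "PrintSchedule", function(x) x@events)

#' @describeIn SyntheticRender-class per-feature ground-truth data.frame.
#' @export
setMethod("groundTruth", "SyntheticRender", function(x) x@groundTruth)

#' @describeIn SyntheticRender-class extract one channel as a matrix;
#'   `channel` may be a channel index or a material id.
#' @param channel integer index or material id.
#' @export
setMethod("channelImage", "SyntheticRender", function(x, channel) {
  if (is.character(channel)) channel <- x@channelMap[[channel]]
  x@image[, , channel]
})

#' @describeIn MorphometryReport-class vector of post/hole centroid
#'   alignment errors (um).
#' @export
setMethod("alignmentErrors", "MorphometryReport",
          function(x) x@alignment$error)

#' @describeIn MorphometryReport-class pooled fraction of alignment errors
#'   strictly below the threshold.
#' @export
setMethod("fractionBelowThreshold", "MorphometryReport",
          function(x) x@fractionBelowThreshold)

setMethod("show", "ProjectorConfig", function(object) {
  cat(sprintf(
    "ProjectorConfig: %d x %d px, %.0f um/px, %.1f mW/cm^2, %.0f nm\n",
    object@resolution[1], object@resolution[2], object@pixelPitch,
    object@intensity, object@wavelength))
})

setMethod("show", "PrintDesign", function(object) {
  cat(sprintf("PrintDesign: %d layer(s), %d material(s), build area %.0f x %.0f um\n",
              length(object@layers), nrow(object@materials),
              object@buildArea[1], object@buildArea[2]))
  for (l in object@layers) {
    nsh <- vapply(l$regions, length, integer(1))
    cat(sprintf("  layer %d (%.0f um, %s): %s\n", l$index, l$thickness,
                l$mode,
                paste(sprintf("%s[%d]", names(nsh), nsh), collapse = ", ")))
  }
})

setMethod("show", "Mask", function(object) {
  cat(sprintf("Mask: layer %d, material '%s', %d x %d px @ %.0f um/px, %.1f%% exposed\n",
              object@layerIndex, object@material, ncol(object@raster),
              nrow(object@raster), object@pixelPitch,
              100 * mean(object@raster) / 255))
})

setMethod("show", "MaskStack", function(object) {
  cat(sprintf("MaskStack: %d mask(s)\n", length(object@masks)))
  for (m in object@masks)
    cat(sprintf("  layer %d / %s\n", m@layerIndex, m@material))
})

setMethod("show", "DoseModel", function(object) {
  cat(sprintf("DoseModel @ %.0f mW/cm^2 (%s):\n", object@referenceIntensity,
              if (object@interpolate) "interpolating" else "table-only"))
  for (i in seq_along(object@thickness))
    cat(sprintf("  %4.0f um -> %5.1f s\n", object@thickness[i],
                object@time[i]))
})

setMethod("show", "PrintSchedule", function(object) {
  tab <- table(object@events$kind)
  cat(sprintf("PrintSchedule (%s rinse policy): %d events [%s]\n",
              object@rinsePolicy, nrow(object@events),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SyntheticRender", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SyntheticRender: %d x %d px x %d channel(s) @ %.1f um/px, %d feature(s), seed %d\n",
    d[2], d[1], d[3], object@pixelSize, nrow(object@groundTruth),
    object@seed))
})

setMethod("show", "MorphometryReport", function(object) {
  cat("MorphometryReport\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %-24s mean %9.3f  sd %8.3f  n %d\n",
                s$class[i], s$metric[i], s$mean[i], s$sd[i], s$n[i]))
  cat(sprintf("  alignment: %d pair(s), %.1f%% of errors < %.0f um (%s)\n",
              nrow(object@alignment),
              100 * object@fractionBelowThreshold, object@threshold,
              object@thresholdProvenance))
  if (length(object@perBatchFraction))
    cat(sprintf("  per batch: %s\n",
                paste(sprintf("%s: %.1f%%", names(object@perBatchFraction),
                              100 * object@perBatchFraction),
                      collapse = ", ")))
})
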
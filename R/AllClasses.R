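#' @import methods
NULL

#' Projector configuration
#'
#' Describes the DLP projection system used to pattern photomasks: the
#' physical size of one projected pixel at the build plane, the native
#' display resolution, and the measured irradiance at the build plane.
#'
#' @slot pixelPitch numeric(1). Projected pixel size at the build plane
#'   (um per pixel).
#' @slot resolution integer(2). Display resolution as (width, height) in
#'   pixels.
#' @slot intensity numeric(1). Irradiance at the build plane (mW/cm^2).
#' @slot wavelength numeric(1). Nominal LED/lamp wavelength (nm),
#'   informational only.
#'
#' @examples
#' ProjectorConfig(pixelPitch = 50, resolution = c(1280L, 800L),
#'                 intensity = 16.5, wavelength = 405)
#' @export
setClass("ProjectorConfig",
  representation(
    pixelPitch = "numeric",
    resolution = "integer",
    intensity  = "numeric",
    wavelength = "numeric"
  )
)

setValidity("ProjectorConfig", function(object) {
  msg <- character()
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number (um/px)")
  if (length(object@resolution) != 2L || any(object@resolution < 1L))
    msg <- c(msg, "resolution must be two positive integers (width, height)")
  if (length(object@intensity) != 1L || !is.finite(object@intensity) ||
      object@intensity <= 0)
    msg <- c(msg, "intensity must be a single positive irradiance (mW/cm^2)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProjectorConfig Constructor.
#' @param pixelPitch,resolution,intensity,wavelength see slots.
#' @export
ProjectorConfig <- function(pixelPitch = 50, resolution = c(1280L, 800L),
                            intensity = 16.5, wavelength = 405) {
  new("ProjectorConfig",
      pixelPitch = as.numeric(pixelPitch),
      resolution = as.integer(resolution),
      intensity  = as.numeric(intensity),
      wavelength = as.numeric(wavelength))
}

#' Multi-material layered print design
#'
#' The central design container: an ordered stack of layers, each holding
#' per-material 2-D regions (in a continuous um design frame with origin at
#' the build-area corner), the material table for the bioink sled, the
#' build-area extent, and the projector that will rasterize the design.
#'
#' Layers are plain lists created by [layerSpec()]; regions map material ids
#' to lists of shapes ([diskShape()], [annulusShape()], [rectShape()],
#' [polygonShape()]). Shapes flagged `negative = TRUE` are subtracted from
#' the union of positive shapes of the same region (constructive geometry),
#' which is how the open-lattice region of the checkerboard test article is
#' built so that posts and holes are exactly complementary.
#'
#' @slot layers list of layer specifications, bottom first, indices
#'   consecutive from 0.
#' @slot materials data.frame with columns `id`, `label`, `dropletIndex`
#'   describing the bioink droplets on the sled (at most 4).
#' @slot buildArea numeric(2). Width and height of the build area (um).
#' @slot projector [ProjectorConfig-class].
#' @slot metadata list of generator-specific annotations (e.g. the nominal
#'   post centers and pitch of a checkerboard design).
#'
#' @seealso [makeCheckerboardDesign()], [makePresetDesign()],
#'   [buildMaskStack()]
#' @export
setClass("PrintDesign",
  representation(
    layers    = "list",
    materials = "data.frame",
    buildArea = "numeric",
    projector = "ProjectorConfig",
    metadata  = "list"
  )
)

setValidity("PrintDesign", function(object) {
  msg <- character()
  mt <- object@materials
  if (!all(c("id", "label", "dropletIndex") %in% names(mt)))
    msg <- c(msg, "materials must have columns id, label, dropletIndex")
  else {
    if (anyDuplicated(mt$id))
      msg <- c(msg, "material ids must be unique")
    if (nrow(mt) > 4L)
      msg <- c(msg, sprintf(
        "material count %d > 4: the sled holds at most 4 bioinks", nrow(mt)))
    if (any(mt$dropletIndex < 0L))
      msg <- c(msg, "dropletIndex must be >= 0")
  }
  if (length(object@buildArea) != 2L || any(object@buildArea <= 0))
    msg <- c(msg, "buildArea must be two positive lengths (um)")
  idx <- vapply(object@layers, function(l) l$index, numeric(1))
  if (length(idx) && !identical(as.integer(idx), seq_along(idx) - 1L))
    msg <- c(msg, "layer indices must be consecutive from 0")
  for (l in object@layers) {
    if (!is.finite(l$thickness) || l$thickness <= 0)
      msg <- c(msg, sprintf("layer %d: thickness must be > 0", l$index))
    bad <- setdiff(names(l$regions), mt$id)
    if (length(bad))
      msg <- c(msg, sprintf("layer %d references unknown material(s): %s",
                            l$index, paste(bad, collapse = ", ")))
    for (mid in names(l$regions)) {
      for (sh in l$regions[[mid]]) {
        bb <- shapeBBox(sh)
        if (bb[1] < -1e-9 || bb[2] < -1e-9 ||
            bb[3] > object@buildArea[1] + 1e-9 ||
            bb[4] > object@buildArea[2] + 1e-9)
          msg <- c(msg, sprintf(
            "layer %d, material '%s': %s shape extends beyond build area",
            l$index, mid, sh$kind))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Photomask raster stack
#'
#' One 8-bit grayscale mask per (layer, material-with-nonempty-region) pair,
#' in layer-major order (then sled droplet order within a layer), at the
#' projector's native resolution. Pixel value 255 means full exposure.
#'
#' @slot masks list of `Mask` objects (see [rasterizeLayer()]).
#' @slot design the [PrintDesign-class] the stack was built from.
#' @seealso [buildMaskStack()], [writeMaskStack()]
#' @export
setClass("MaskStack",
  representation(masks = "list", design = "PrintDesign"))

setValidity("MaskStack", function(object) {
  msg <- character()
  for (m in object@masks) {
    if (!is(m, "Mask")) { msg <- c(msg, "masks must be Mask objects"); break }
  }
  li <- vapply(object@masks, function(m) m@layerIndex, numeric(1))
  if (is.unsorted(li))
    msg <- c(msg, "masks must be in layer-major order")
  if (length(msg)) msg else TRUE
})

#' Single-material photomask for one layer
#'
#' @slot raster integer matrix, values 0-255 (255 = full exposure); rows are
#'   image rows (row 1 maps to the design-frame edge at y = 0; rasters are
#'   flipped vertically on file export so that file row 0 is the top).
#' @slot pixelPitch numeric(1), um per pixel.
#' @slot layerIndex integer(1), 0-based layer index.
#' @slot material character(1), material id.
#' @export
setClass("Mask",
  representation(raster = "matrix", pixelPitch = "numeric",
                 layerIndex = "integer", material = "character"))

setValidity("Mask", function(object) {
  msg <- character()
  r <- object@raster
  if (any(r < 0 | r > 255)) msg <- c(msg, "raster values must lie in [0, 255]")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
  if (length(msg)) msg else TRUE
})

#' Exposure dose model
#'
#' Lookup table of exposure times by layer thickness at a reference
#' irradiance, with optional linear interpolation in thickness. Queries at a
#' different irradiance scale the time by `reference / intensity`
#' (constant-dose assumption: time x intensity is held fixed).
#'
#' @slot thickness numeric vector of layer thicknesses (um), sorted.
#' @slot time numeric vector of exposure times (s) at the reference
#'   irradiance.
#' @slot referenceIntensity numeric(1), mW/cm^2.
#' @slot interpolate logical(1); if FALSE only tabulated thicknesses are
#'   accepted.
#' @seealso [exposureTime()]
#' @export
setClass("DoseModel",
  representation(thickness = "numeric", time = "numeric",
                 referenceIntensity = "numeric", interpolate = "logical"))

setValidity("DoseModel", function(object) {
  msg <- character()
  if (length(object@thickness) != length(object@time))
    msg <- c(msg, "thickness and time must have equal length")
  if (any(object@thickness <= 0)) msg <- c(msg, "thicknesses must be > 0")
  if (any(object@time <= 0)) msg <- c(msg, "times must be > 0")
  if (is.unsorted(object@thickness, strictly = TRUE))
    msg <- c(msg, "thicknesses must be strictly increasing")
  if (object@referenceIntensity <= 0)
    msg <- c(msg, "referenceIntensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Compiled print schedule
#'
#' Ordered machine-event sequence (Z moves, sled moves, exposures, rinses)
#' realizing a multi-material print. Events live in a data.frame with
#' columns `kind` (LOWER, EXPOSE, RAISE, SLED_MOVE, RINSE, WICK), `z` (um,
#' plate height target or current), `material`, `maskIndex`, `sledTarget`
#' (droplet index, or -1 for the rinse station), `duration` (s estimate) and
#' `note`.
#'
#' @slot events data.frame as described above.
#' @slot design the source [PrintDesign-class].
#' @slot rinsePolicy "strict" (rinse at every material switch) or
#'   "as_described" (no rinse when leaving the dye-free base droplet).
#' @seealso [compileSchedule()], [validateSchedule()], [estimateDuration()]
#' @export
setClass("PrintSchedule",
  representation(events = "data.frame", design = "PrintDesign",
                 rinsePolicy = "character"))

setValidity("PrintSchedule", function(object) {
  msg <- character()
  need <- c("kind", "z", "material", "maskIndex", "sledTarget",
            "duration", "note")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, paste("events must have columns:",
                        paste(need, collapse = ", ")))
  if (!object@rinsePolicy %in% c("strict", "as_described"))
    msg <- c(msg, "rinsePolicy must be 'strict' or 'as_described'")
  if (length(msg)) msg else TRUE
})

#' Synthetic fluorescence render of a printed feature layer
#'
#' A multi-channel microscope-like image of the feature layer of a design,
#' with per-feature ground truth (perturbed, as-drawn geometry, not the
#' nominal design).
#'
#' @slot image numeric array (rows, cols, channels), intensities in [0, 1].
#' @slot groundTruth data.frame with columns `featureId`, `class`
#'   (post/hole), `x`, `y`, `diameter` (um, as drawn) and `pairId` linking
#'   each post to its nesting hole.
#' @slot pixelSize numeric(1), um per image pixel (microscope scale).
#' @slot channelMap named integer vector, material id -> channel index.
#' @slot seed integer(1) used for all stochastic perturbations.
#' @seealso [renderFeatureLayer()]
#' @export
setClass("SyntheticRender",
  representation(image = "array", groundTruth = "data.frame",
                 pixelSize = "numeric", channelMap = "integer",
                 seed = "integer"))

setValidity("SyntheticRender", function(object) {
  msg <- character()
  if (length(dim(object@image)) != 3L)
    msg <- c(msg, "image must be a (rows, cols, channels) array")
  gt <- object@groundTruth
  need <- c("featureId", "class", "x", "y", "diameter", "pairId")
  if (!all(need %in% names(gt)))
    msg <- c(msg, paste("groundTruth must have columns:",
                        paste(need, collapse = ", ")))
  else {
    pid_post <- gt$pairId[gt$class == "post"]
    pid_hole <- gt$pairId[gt$class == "hole"]
    if (!setequal(pid_post, pid_hole) || anyDuplicated(pid_post) ||
        anyDuplicated(pid_hole))
      msg <- c(msg, "pairId must be a bijection between posts and holes")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (anyDuplicated(object@channelMap))
    msg <- c(msg, "two materials mapped to the same channel")
  if (length(msg)) msg else TRUE
})

#' Morphometric fidelity report
#'
#' Per-class summary statistics (mean, sd, n) of equivalent diameter,
#' circularity and nearest-neighbor distance, the list of post/hole centroid
#' alignment errors, and the fraction of alignment errors strictly below a
#' resolution threshold (by default the projector pixel size).
#'
#' @slot summary data.frame with columns `class`, `metric`, `mean`, `sd`,
#'   `n`.
#' @slot alignment data.frame of post/hole pairs with columns `postLabel`,
#'   `holeLabel`, `error` (um) and optionally `batch`.
#' @slot fractionBelowThreshold numeric(1) in [0, 1] (strict inequality at
#'   the threshold); pooled across batches.
#' @slot perBatchFraction named numeric vector (one entry per batch, empty
#'   when no batch labels were supplied).
#' @slot threshold numeric(1), um.
#' @slot thresholdProvenance character(1), e.g. "projector pixel size".
#' @seealso [summarizeMorphometry()]
#' @export
setClass("MorphometryReport",
  representation(summary = "data.frame", alignment = "data.frame",
                 fractionBelowThreshold = "numeric",
                 perBatchFraction = "numeric",
                 threshold = "numeric", thresholdProvenance = "character"))

setValidity("MorphometryReport", function(object) {
  msg <- character()
  f <- object@fractionBelowThreshold
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    msg <- c(msg, "fractionBelowThreshold must lie in [0, 1]")
  if (object@threshold <= 0) msg <- c(msg, "threshold must be > 0")
  if (length(msg)) msg else TRUE
})
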
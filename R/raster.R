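#' Rasterize one material region of one layer into a photomask
#'
#' Converts the continuous-geometry region of `material` in `layer` into an
#' 8-bit grayscale mask at the projector's native resolution. Each pixel
#' value is `round(255 * f)` where `f` is the fraction of `supersample^2`
#' sub-pixel sample points covered by the region — grayscale edges are
#' deliberate, mirroring the instrument's grayscale photomasks. The design
#' frame origin maps to the raster corner at row 1, column 1; on file export
#' rasters are flipped so that the image top corresponds to maximum y.
#'
#' @param layer a [layerSpec()] object.
#' @param material material id; the layer may hold an empty region for it.
#' @param design the parent [PrintDesign-class] (supplies build area and
#'   projector).
#' @param supersample sub-pixel samples per pixel edge (default 4).
#' @return a [Mask-class].
#' @export
rasterizeLayer <- function(layer, material, design, supersample = 4L) {
  proj <- design@projector
  shapes <- layer$regions[[material]]
  if (is.null(shapes) && !material %in% design@materials$id)
    stop("unknown material: ", material)
  ncol <- proj@resolution[1]
  nrow <- proj@resolution[2]
  if (design@buildArea[1] > ncol * proj@pixelPitch + 1e-9 ||
      design@buildArea[2] > nrow * proj@pixelPitch + 1e-9)
    stop("build area exceeds the projector's addressable field")
  for (sh in shapes %||% list()) {
    bb <- shapeBBox(sh)
    if (bb[1] < -1e-9 || bb[2] < -1e-9 ||
        bb[3] > design@buildArea[1] + 1e-9 ||
        bb[4] > design@buildArea[2] + 1e-9)
      stop(sprintf("%s shape at (%.0f, %.0f) extends beyond the build area",
                   sh$kind, sh$center[1], sh$center[2]))
  }
  cov <- if (length(shapes))
    coverageMatrix(shapes, nrow, ncol, proj@pixelPitch, supersample)
  else matrix(0, nrow, ncol)
  new("Mask", raster = matrix(as.integer(round(255 * cov)), nrow, ncol),
      pixelPitch = proj@pixelPitch, layerIndex = layer$index,
      material = material)
}

#' Build the full photomask stack of a design
#'
#' One mask per (layer, material) pair with a nonempty region, ordered
#' layer-major and, within a layer, by sled droplet index. Within every
#' layer the per-pixel sum of covered fractions across materials is checked
#' to stay at or below 1 (no double exposure of co-planar regions).
#'
#' @param design [PrintDesign-class].
#' @param supersample sub-pixel samples per pixel edge.
#' @param tol tolerance on the per-pixel coverage sum (absorbs sub-pixel
#'   sampling noise along shared boundaries).
#' @return a [MaskStack-class].
#' @export
buildMaskStack <- function(design, supersample = 4L, tol = 1 / 255 + 1e-9) {
  drop <- stats::setNames(design@materials$dropletIndex,
                          design@materials$id)
  masks <- list()
  for (l in design@layers) {
    mids <- names(l$regions)[vapply(l$regions, length, integer(1)) > 0]
    mids <- mids[order(drop[mids])]
    layerMasks <- lapply(mids, rasterizeLayer, layer = l, design = design,
                         supersample = supersample)
    if (length(layerMasks) > 1L) {
      tot <- Reduce(`+`, lapply(layerMasks, function(m) m@raster / 255))
      if (max(tot) > 1 + tol)
        stop(sprintf(
          "layer %d: co-planar materials overlap (max coverage sum %.3f)",
          l$index, max(tot)))
    }
    masks <- c(masks, layerMasks)
  }
  new("MaskStack", masks = masks, design = design)
}

#' Write a mask stack to 8-bit grayscale PNGs plus a JSON manifest
#'
#' Files are named `layer{idx}_mat{droplet}.png` (zero-padded layer index);
#' rasters are flipped vertically so that file row 0 is the top of the
#' build area (maximum y). The manifest records pixel pitch, ordering and a
#' design hash.
#'
#' @param stack [MaskStack-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
writeMaskStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  drop <- stats::setNames(stack@design@materials$dropletIndex,
                          stack@design@materials$id)
  entries <- lapply(stack@masks, function(m) {
    fn <- sprintf("layer%03d_mat%d.png", m@layerIndex, drop[[m@material]])
    png::writePNG(m@raster[nrow(m@raster):1, , drop = FALSE] / 255,
                  file.path(dir, fn))
    list(file = fn, layer = m@layerIndex, material = m@material,
         droplet = unname(drop[[m@material]]))
  })
  manifest <- list(pixelPitch = stack@design@projector@pixelPitch,
                   designHash = designHash(stack@design),
                   masks = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Stable content hash of a design (geometry + materials + projector).
designHash <- function(design) {
  rlang::hash(list(lapply(design@layers, unclass),
                   design@materials, design@buildArea,
                   c(design@projector@pixelPitch,
                     design@projector@resolution,
                     design@projector@intensity)))
}
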
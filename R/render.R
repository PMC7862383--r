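#' Imaging configuration for the synthetic renderer
#'
#' Microscope-side parameters, independent of the projector: image pixel
#' size, the material-to-channel assignment, an isotropic Gaussian blur
#' standing in for the point-spread function, additive Gaussian noise and a
#' uniform background, and the seed that drives every stochastic step.
#'
#' @param pixelSize um per image pixel (default 5, so a 500 um post spans
#'   ~100 px — enough for stable perimeter estimation).
#' @param channelMap named integer vector, material id -> channel index;
#'   channels must be distinct.
#' @param blurSigma Gaussian PSF sigma (um); 0 disables blur.
#' @param noiseSd additive Gaussian noise sd as a fraction of full scale,
#'   in [0, 1).
#' @param background uniform background level, fraction of full scale.
#' @param foreground foreground intensity of crosslinked regions.
#' @param seed integer seed.
#' @param supersample sub-pixel coverage samples per pixel edge.
#' @return a validated `ImagingConfig` list.
#' @export
imagingConfig <- function(pixelSize = 5,
                          channelMap = c(post = 1L, lattice = 2L),
                          blurSigma = 2, noiseSd = 0.01, background = 0.05,
                          foreground = 0.8, seed = 1L, supersample = 2L) {
  stopifnot(pixelSize > 0, noiseSd >= 0, noiseSd < 1,
            background >= 0, background < 1, foreground > background)
  if (anyDuplicated(channelMap))
    stop("channel collision: two materials mapped to one channel")
  structure(list(pixelSize = pixelSize,
                 channelMap = stats::setNames(as.integer(channelMap),
                                              names(channelMap)),
                 blurSigma = blurSigma, noiseSd = noiseSd,
                 background = background, foreground = foreground,
                 seed = as.integer(seed),
                 supersample = as.integer(supersample)),
            class = "ImagingConfig")
}

#' Geometric-fidelity perturbation model
#'
#' Error sources applied to the nominal design before rendering, emulating
#' the placement and shape errors of a physical print. By default jitter
#' displaces posts only, holes staying at their design positions, so the
#' post/hole centroid alignment error isolates inter-material registration.
#'
#' @param placementJitterSd per-axis Gaussian placement jitter sd (um).
#' @param diameterErrorSd per-feature Gaussian diameter error sd (um).
#' @param edgeRoughness boundary perturbation amplitude (um), realized as a
#'   small sum of radial harmonics on disk outlines.
#' @param jitterHoles also jitter hole positions (independently)?
#' @return a validated `FidelityModel` list.
#' @export
fidelityModel <- function(placementJitterSd = 0, diameterErrorSd = 0,
                          edgeRoughness = 0, jitterHoles = FALSE) {
  stopifnot(placementJitterSd >= 0, diameterErrorSd >= 0,
            edgeRoughness >= 0)
  structure(list(placementJitterSd = placementJitterSd,
                 diameterErrorSd = diameterErrorSd,
                 edgeRoughness = edgeRoughness,
                 jitterHoles = isTRUE(jitterHoles)),
            class = "FidelityModel")
}

perturbDisk <- function(sh, jitterSd, diamSd, rough) {
  ctr <- sh$center + if (jitterSd > 0) stats::rnorm(2, 0, jitterSd) else c(0, 0)
  diam <- sh$diameter + if (diamSd > 0) stats::rnorm(1, 0, diamSd) else 0
  diam <- max(diam, 1e-6)
  if (rough > 0) {
    harm <- 3:8
    roughDiskShape(ctr, diam, rough, harm,
                   stats::runif(length(harm), 0, 2 * pi),
                   negative = sh$negative)
  } else diskShape(ctr, diam, negative = sh$negative)
}

#' Render a synthetic fluorescence image of a printed feature layer
#'
#' Draws each material region of the checkerboard-style feature layer into
#' its own channel at uniform foreground intensity — after applying the
#' fidelity perturbations — then blurs, adds background and Gaussian noise.
#' The emitted ground truth records the perturbed (as-drawn) centroids and
#' diameters, with a pair id linking every post to the hole it nests in.
#' The same seed and configuration reproduce the image bit for bit.
#'
#' @param design a checkerboard design from [makeCheckerboardDesign()].
#' @param imaging an [imagingConfig()].
#' @param fidelity a [fidelityModel()].
#' @return a [SyntheticRender-class].
#' @export
renderFeatureLayer <- function(design, imaging = imagingConfig(),
                               fidelity = fidelityModel()) {
  cb <- design@metadata$checkerboard
  if (is.null(cb))
    stop("renderFeatureLayer requires a checkerboard-style design")
  feat <- design@layers[[cb$featureLayer + 1L]]
  mats <- names(feat$regions)
  missing <- setdiff(mats, names(imaging$channelMap))
  if (length(missing))
    stop("channelMap does not cover material(s): ",
         paste(missing, collapse = ", "))
  ps <- imaging$pixelSize
  ncol <- as.integer(ceiling(design@buildArea[1] / ps))
  nrow <- as.integer(ceiling(design@buildArea[2] / ps))
  nchan <- max(imaging$channelMap)

  withSeed(imaging$seed, {
    nPost <- nrow(cb$centers)
    postShift <- if (fidelity$placementJitterSd > 0)
      matrix(stats::rnorm(2 * nPost, 0, fidelity$placementJitterSd),
             ncol = 2) else matrix(0, nPost, 2)
    holeShift <- if (fidelity$jitterHoles &&
                     fidelity$placementJitterSd > 0)
      matrix(stats::rnorm(2 * nPost, 0, fidelity$placementJitterSd),
             ncol = 2) else matrix(0, nPost, 2)

    gt <- list()
    img <- array(0, dim = c(nrow, ncol, nchan))
    postIdx <- 0L
    holeIdx <- 0L
    for (mid in mats) {
      shapes <- feat$regions[[mid]]
      drawn <- vector("list", length(shapes))
      for (k in seq_along(shapes)) {
        sh <- shapes[[k]]
        if (sh$kind == "disk" && !isTRUE(sh$negative)) {
          postIdx <- postIdx + 1L
          sh2 <- sh
          sh2$center <- sh$center + postShift[postIdx, ]
          drawn[[k]] <- perturbDisk(sh2, 0, fidelity$diameterErrorSd,
                                    fidelity$edgeRoughness)
          gt[[length(gt) + 1L]] <- data.frame(
            class = "post", x = drawn[[k]]$center[1],
            y = drawn[[k]]$center[2], diameter = drawn[[k]]$diameter,
            pairId = postIdx, stringsAsFactors = FALSE)
        } else if (sh$kind == "disk" && isTRUE(sh$negative)) {
          holeIdx <- holeIdx + 1L
          sh2 <- sh
          sh2$center <- sh$center + holeShift[holeIdx, ]
          drawn[[k]] <- perturbDisk(sh2, 0, fidelity$diameterErrorSd,
                                    fidelity$edgeRoughness)
          gt[[length(gt) + 1L]] <- data.frame(
            class = "hole", x = drawn[[k]]$center[1],
            y = drawn[[k]]$center[2], diameter = drawn[[k]]$diameter,
            pairId = holeIdx, stringsAsFactors = FALSE)
        } else {
          drawn[[k]] <- sh
        }
      }
      cov <- coverageMatrix(drawn, nrow, ncol, ps, imaging$supersample)
      ch <- imaging$channelMap[[mid]]
      img[, , ch] <- imaging$background +
        (imaging$foreground - imaging$background) * cov
    }
    if (imaging$blurSigma > 0) {
      sigmaPx <- imaging$blurSigma / ps
      for (ch in seq_len(nchan))
        img[, , ch] <- EBImage::gblur(img[, , ch], sigma = sigmaPx)
    }
    if (imaging$noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, imaging$noiseSd)
    img <- clip01(img)

    gtd <- do.call(rbind, gt)
    gtd <- cbind(featureId = seq_len(nrow(gtd)), gtd)
    new("SyntheticRender", image = img, groundTruth = gtd,
        pixelSize = ps, channelMap = imaging$channelMap,
        seed = imaging$seed)
  })
}

#' Write / read per-feature ground truth as CSV
#'
#' One row per feature: `featureId`, `class`, `x`, `y`, `diameter`,
#' `pairId`. The table round-trips losslessly (full double precision).
#'
#' @param gt a ground-truth data.frame (e.g. `groundTruth(render)`).
#' @param path CSV path.
#' @return `path` (`writeGroundTruth`) or the data.frame
#'   (`readGroundTruth`).
#' @export
writeGroundTruth <- function(gt, path) {
  if (is(gt, "SyntheticRender")) gt <- gt@groundTruth
  if (!nrow(gt)) stop("ground truth has no records")
  for (cl in c("post", "hole")) {
    p <- gt$pairId[gt$class == cl]
    if (anyDuplicated(p))
      stop("duplicate pair ids among ", cl, " records")
  }
  utils::write.csv(format(gt, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
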
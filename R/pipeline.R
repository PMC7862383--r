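#' Morphometric analysis of a two-channel checkerboard image
#'
#' Runs the full measurement chain on a rendered (or acquired) post/lattice
#' image pair: segment posts from the post channel and holes from the
#' lattice channel, measure both classes, pair posts with their nesting
#' holes by mutual nearest neighbor (gated at pitch/2), and summarize
#' against the resolution threshold.
#'
#' @param postImg,latticeImg 2-D channel matrices in [0, 1]; alternatively
#'   pass a [SyntheticRender-class] as `postImg` (channels are pulled from
#'   its channel map).
#' @param pixelSize um per pixel (taken from the render if one is given).
#' @param pitch nominal nearest-neighbor pitch (um); sets the pairing gate.
#' @param threshold resolution threshold for the alignment fraction (um).
#' @param segmentation threshold rule passed to [segmentFeatures()].
#' @param minArea minimum feature area (um^2).
#' @return list with `measurements`, `pairs` (including unpaired labels)
#'   and `report` (a [MorphometryReport-class]).
#' @export
analyzeCheckerboard <- function(postImg, latticeImg = NULL, pixelSize = NULL,
                                pitch = 1000, threshold = 50,
                                segmentation = "otsu", minArea = 2000) {
  if (is(postImg, "SyntheticRender")) {
    render <- postImg
    postImg <- channelImage(render, "post")
    latticeImg <- channelImage(render, "lattice")
    pixelSize <- render@pixelSize
  }
  stopifnot(!is.null(latticeImg), !is.null(pixelSize))
  postLab <- segmentFeatures(postImg, pixelSize, "post",
                             threshold = segmentation, minArea = minArea)
  holeLab <- segmentFeatures(latticeImg, pixelSize, "hole",
                             threshold = segmentation, minArea = minArea)
  posts <- measureFeatures(postLab)
  holes <- measureFeatures(holeLab)
  pairing <- pairPostsHoles(posts, holes, maxPairDistance = pitch / 2)
  report <- summarizeMorphometry(rbind(posts, holes), pairing$pairs,
                                 threshold = threshold)
  list(measurements = rbind(posts, holes), pairs = pairing,
       report = report)
}

resolveConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(x, field, where) {
    if (is.null(x)) stop("config is missing required field: ", where,
                         "$", field)
    x
  }
  dz <- config$design %||% list()
  need(config$seed, "seed", "")
  need(dz$type %||% "checkerboard", "type", "design")
  im <- config$imaging %||% list()
  need(im$pixel_size, "pixel_size", "imaging")
  config
}

#' Run the full design-to-report pipeline
#'
#' Executes design generation, mask rasterization, schedule compilation and
#' validation, synthetic rendering and morphometric analysis from a single
#' YAML (or list) configuration, writing every artifact under one output
#' directory: photomask PNGs + manifest, schedule JSON + log, multi-page
#' TIFF image, ground-truth CSV, measurement and pair CSVs, a JSON report,
#' the resolved config, and a run log. All randomness flows from
#' `config$seed`, so re-running an archived config reproduces the outputs
#' bit for bit.
#'
#' @param config path to a YAML config, or an equivalent nested list. See
#'   the packaged example under `system.file("extdata", "fidelity-run.yaml",
#'   package = "mmsla")`.
#' @param outdir output directory; defaults to `config$outdir`, with a
#'   timestamped subdirectory appended unless `timestamp = FALSE`.
#' @param timestamp append a `run-<timestamp>` subdirectory?
#' @return invisibly, a list with the design, mask stack, schedule, render,
#'   analysis and the output directory.
#' @export
runPipeline <- function(config, outdir = NULL, timestamp = FALSE) {
  config <- resolveConfig(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  if (timestamp)
    outdir <- file.path(outdir, format(Sys.time(), "run-%Y%m%d-%H%M%S"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  dz <- config$design %||% list()
  pz <- config$projector %||% list()
  proj <- ProjectorConfig(
    pixelPitch = pz$pixel_pitch %||% 50,
    resolution = unlist(pz$resolution %||% c(1280L, 800L)),
    intensity = pz$intensity %||% 16.5,
    wavelength = pz$wavelength %||% 405)
  design <- stage("design", {
    if (identical(dz$type %||% "checkerboard", "checkerboard"))
      makeCheckerboardDesign(
        postDiameter = dz$post_diameter %||% 500,
        pitch = dz$pitch %||% 1000,
        rows = dz$rows %||% 8L, cols = dz$cols %||% 8L,
        baseThickness = dz$base_thickness %||% 300,
        nBaseLayers = dz$n_base_layers %||% 1L,
        featureThickness = dz$feature_thickness %||% 100,
        projector = proj)
    else
      do.call(makePresetDesign,
              c(list(preset = dz$type, projector = proj),
                dz[setdiff(names(dz), "type")]))
  })
  note("design: %d layers, %d materials", length(design@layers),
       nrow(design@materials))

  stack <- stage("masks", buildMaskStack(design))
  writeMaskStack(stack, file.path(outdir, "masks"))
  note("masks: %d written", length(stack@masks))

  dmz <- config$dose_model %||% list()
  model <- if (length(dmz))
    DoseModel(as.numeric(names(dmz$entries)),
              as.numeric(unlist(dmz$entries)),
              referenceIntensity = dmz$reference_intensity %||% 10,
              interpolate = dmz$interpolate %||% TRUE)
  else defaultDoseModel()
  sched <- stage("schedule", compileSchedule(
    design, stack, model,
    rinsePolicy = (config$schedule %||% list())$rinse_policy %||% "strict"))
  viol <- validateSchedule(sched)
  if (nrow(viol))
    stop("pipeline stage 'schedule' produced an invalid schedule: ",
         paste(viol$message, collapse = "; "))
  writeSchedule(sched, file.path(outdir, "schedule.json"))
  note("schedule: %d events, 0 violations", nrow(sched@events))

  im <- config$imaging %||% list()
  fz <- config$fidelity %||% list()
  chm <- im$channels %||% list(post = 1L, lattice = 2L)
  imaging <- imagingConfig(
    pixelSize = im$pixel_size,
    channelMap = stats::setNames(as.integer(unlist(chm)), names(chm)),
    blurSigma = im$blur_sigma %||% 2,
    noiseSd = im$noise_sd %||% 0.01,
    background = im$background %||% 0.05,
    foreground = im$foreground %||% 0.8,
    seed = config$seed,
    supersample = im$supersample %||% 2L)
  fidelity <- fidelityModel(
    placementJitterSd = fz$placement_jitter_sd %||% 0,
    diameterErrorSd = fz$diameter_error_sd %||% 0,
    edgeRoughness = fz$edge_roughness %||% 0,
    jitterHoles = fz$jitter_holes %||% FALSE)
  render <- stage("render", renderFeatureLayer(design, imaging, fidelity))
  writeChannelImage(render, file.path(outdir, "render.tif"))
  writeGroundTruth(render, file.path(outdir, "ground_truth.csv"))
  note("render: %d x %d px, %d features", dim(render@image)[2],
       dim(render@image)[1], nrow(render@groundTruth))

  mz <- config$morphometry %||% list()
  analysis <- stage("morphometry", analyzeCheckerboard(
    render, pitch = dz$pitch %||% 1000,
    threshold = mz$threshold %||% design@projector@pixelPitch,
    segmentation = mz$segmentation %||% "otsu",
    minArea = mz$min_area %||% 2000))
  writeTable(analysis$measurements, file.path(outdir, "measurements.csv"))
  writeTable(analysis$pairs$pairs, file.path(outdir, "pairs.csv"))
  rep <- analysis$report
  jsonlite::write_json(list(
    package = "mmsla",
    version = as.character(utils::packageVersion("mmsla")),
    seed = config$seed,
    summary = rep@summary,
    fraction_below_threshold = rep@fractionBelowThreshold,
    threshold_um = rep@threshold,
    threshold_provenance = rep@thresholdProvenance,
    n_pairs = nrow(rep@alignment)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  note("morphometry: %d pairs, %.1f%% of alignment errors < %.0f um",
       nrow(rep@alignment), 100 * rep@fractionBelowThreshold,
       rep@threshold)

  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  writeLines(logLines, file.path(outdir, "run.log"))
  invisible(list(design = design, masks = stack, schedule = sched,
                 render = render, analysis = analysis, outdir = outdir))
}
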
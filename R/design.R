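#' Layer specification
#'
#' @param index 0-based layer index (bottom layer first).
#' @param thickness layer thickness (um). Values outside the 50-300 um
#'   range used on the instrument trigger a warning, not an error.
#' @param regions named list: material id -> list of shapes.
#' @param mode "features" or "full_plane" (a full-plane layer exposes the
#'   whole build area in its single material).
#' @return a `LayerSpec` list.
#' @export
layerSpec <- function(index, thickness, regions, mode = "features") {
  mode <- match.arg(mode, c("features", "full_plane"))
  if (thickness <= 0) stop("layer thickness must be > 0")
  if (thickness < 50 || thickness > 300)
    warning(sprintf(
      "layer %d thickness %.0f um lies outside the typical 50-300 um range",
      index, thickness))
  structure(list(index = as.integer(index), thickness = as.numeric(thickness),
                 regions = regions, mode = mode),
            class = "LayerSpec")
}

#' Material table for the bioink sled
#'
#' @param id character vector of unique material ids.
#' @param label free-text labels (e.g. tracer names); recycled if scalar.
#' @param dropletIndex integer sled positions (0 = far-left droplet, by
#'   convention dye-free base material). Defaults to 0, 1, 2, ...
#' @export
materialTable <- function(id, label = id, dropletIndex = seq_along(id) - 1L) {
  data.frame(id = as.character(id), label = rep_len(label, length(id)),
              dropletIndex = as.integer(dropletIndex),
              stringsAsFactors = FALSE)
}

#' Construct a print design
#'
#' @param layers list of [layerSpec()] objects, bottom first.
#' @param materials data.frame from [materialTable()].
#' @param buildArea numeric(2), build-area extent (um); must contain every
#'   shape.
#' @param projector [ProjectorConfig-class].
#' @return a validated [PrintDesign-class].
#' @export
PrintDesign <- function(layers, materials, buildArea,
                        projector = ProjectorConfig(), metadata = list()) {
  layers <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (identical(l$mode, "full_plane")) {
      mid <- names(l$regions)[1]
      l$regions <- stats::setNames(list(list(
        rectShape(buildArea / 2, buildArea[1], buildArea[2]))), mid)
    }
    l
  })
  new("PrintDesign", layers = layers, materials = materials,
      buildArea = as.numeric(buildArea), projector = projector,
      metadata = metadata)
}

#' Hex-packed post/lattice checkerboard design
#'
#' Builds the geometric-fidelity test article: full-plane base layer(s) of a
#' dye-free material, topped by a feature layer holding (a) a hexagonally
#' packed array of cylindrical posts in one material and (b) the
#' complementary open lattice in a second material — the feature plane minus
#' hole disks of the same diameter at the same centers, so posts nest
#' exactly in their holes. Hex packing places rows pitch*sqrt(3)/2 apart
#' with alternate rows shifted by pitch/2; every post's nearest neighbor
#' then sits exactly one pitch away.
#'
#' @param postDiameter post (and hole) diameter, um; must be < pitch.
#' @param pitch nearest-neighbor center distance, um.
#' @param rows,cols number of post rows and columns (>= 1).
#' @param baseThickness thickness of each base layer, um.
#' @param nBaseLayers number of full-plane base layers.
#' @param featureThickness thickness of the post/lattice layer, um.
#' @param projector [ProjectorConfig-class].
#' @param packing "hex" (default) or "square".
#' @param margin clearance between the outermost post edge region and the
#'   build-area boundary, um; default pitch/2.
#' @return [PrintDesign-class] with materials `base`, `post`, `lattice`.
#'
#' @examples
#' d <- makeCheckerboardDesign(postDiameter = 500, pitch = 1000,
#'                             rows = 3, cols = 3)
#' postCenters(d)
#' @export
makeCheckerboardDesign <- function(postDiameter = 500, pitch = 1000,
                                   rows = 8L, cols = 8L,
                                   baseThickness = 300, nBaseLayers = 1L,
                                   featureThickness = 100,
                                   projector = ProjectorConfig(),
                                   packing = c("hex", "square"),
                                   margin = pitch / 2) {
  packing <- match.arg(packing)
  if (postDiameter >= pitch)
    stop("postDiameter must be < pitch: features of ", postDiameter,
         " um would merge at ", pitch, " um spacing")
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  rowStep <- if (packing == "hex") pitch * sqrt(3) / 2 else pitch
  centers <- do.call(rbind, lapply(seq_len(rows) - 1L, function(r) {
    off <- if (packing == "hex" && r %% 2L == 1L) pitch / 2 else 0
    cbind(margin + off + (seq_len(cols) - 1L) * pitch, margin + r * rowStep)
  }))
  maxOff <- if (packing == "hex" && rows > 1L) pitch / 2 else 0
  buildArea <- c(2 * margin + (cols - 1L) * pitch + maxOff,
                 2 * margin + (rows - 1L) * rowStep)
  mats <- materialTable(c("base", "post", "lattice"),
                        label = c("dye-free base", "post tracer",
                                  "lattice tracer"))
  posts <- lapply(seq_len(nrow(centers)), function(k)
    diskShape(centers[k, ], postDiameter))
  holes <- lapply(seq_len(nrow(centers)), function(k)
    diskShape(centers[k, ], postDiameter, negative = TRUE))
  lattice <- c(list(rectShape(buildArea / 2, buildArea[1], buildArea[2])),
               holes)
  base <- lapply(seq_len(nBaseLayers), function(i)
    layerSpec(i - 1L, baseThickness, list(base = list()),
              mode = "full_plane"))
  feat <- layerSpec(nBaseLayers, featureThickness,
                    list(post = posts, lattice = lattice))
  PrintDesign(c(base, list(feat)), mats, buildArea, projector,
              metadata = list(checkerboard = list(
                centers = centers, pitch = pitch,
                postDiameter = postDiameter,
                featureLayer = nBaseLayers, packing = packing)))
}

#' Nominal post centers of a checkerboard design
#'
#' @param design a design from [makeCheckerboardDesign()].
#' @return two-column matrix of (x, y) centers in um.
#' @export
postCenters <- function(design) {
  cb <- design@metadata$checkerboard
  if (is.null(cb)) stop("design does not carry checkerboard metadata")
  cb$centers
}

#' Parametric preset designs
#'
#' Small library of the print architectures exercised on the instrument:
#' post/stem pillars, annulus arrays, a core/shell construct whose cellular
#' core is fully enclosed laterally and vertically by an acellular shell,
#' and a co-planar mosaic of up to 4 materials.
#'
#' @param preset one of "post_stem", "annulus_array", "core_shell",
#'   "mosaic".
#' @param ... preset parameters, all lengths in um:
#'   \describe{
#'     \item{post_stem}{`postDiameter` (default 500), `stemDiameter` (250),
#'       `pitch` (1000), `rows`/`cols` (3), `postThickness` (200),
#'       `stemThickness` (100), `nBaseLayers` (1), `baseThickness` (100).}
#'     \item{annulus_array}{`inner` (500), `outer` (1000), `pitch` (1500),
#'       `rows`/`cols` (2), `thickness` (100), `nBaseLayers` (1).}
#'     \item{core_shell}{`coreDiameter` (1000), `coreLayerThickness` (200),
#'       `shellMargin` (500), `shellLayerThickness` (200),
#'       `nShellLayers` (1, below and above).}
#'     \item{mosaic}{`tile` (1000), `rows`/`cols` (2), `materials`
#'       (character vector, at most 4), `thickness` (100).}
#'   }
#' @param projector [ProjectorConfig-class].
#' @return a validated [PrintDesign-class].
#' @export
makePresetDesign <- function(preset = c("post_stem", "annulus_array",
                                        "core_shell", "mosaic"),
                             ..., projector = ProjectorConfig()) {
  preset <- match.arg(preset)
  p <- list(...)
  get <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  switch(preset,
    post_stem = {
      d <- get("postDiameter", 500); s <- get("stemDiameter", 250)
      pitch <- get("pitch", 1000)
      rows <- get("rows", 3L); cols <- get("cols", 3L)
      if (s >= d) stop("stemDiameter must be < postDiameter")
      margin <- pitch / 2
      centers <- as.matrix(expand.grid(
        x = margin + (seq_len(cols) - 1L) * pitch,
        y = margin + (seq_len(rows) - 1L) * pitch))
      ba <- c(2 * margin + (cols - 1L) * pitch,
              2 * margin + (rows - 1L) * pitch)
      mats <- materialTable(c("base", "ink"))
      mk <- function(diam) lapply(seq_len(nrow(centers)), function(k)
        diskShape(centers[k, ], diam))
      layers <- c(
        lapply(seq_len(get("nBaseLayers", 1L)), function(i)
          layerSpec(i - 1L, get("baseThickness", 100),
                    list(base = list()), mode = "full_plane")),
        list(layerSpec(get("nBaseLayers", 1L), get("postThickness", 200),
                       list(ink = mk(d))),
             layerSpec(get("nBaseLayers", 1L) + 1L,
                       get("stemThickness", 100), list(ink = mk(s)))))
      PrintDesign(layers, mats, ba, projector)
    },
    annulus_array = {
      inner <- get("inner", 500); outer <- get("outer", 1000)
      if (!(inner > 0 && inner < outer))
        stop("annulus requires 0 < inner < outer diameter")
      pitch <- get("pitch", 1500)
      rows <- get("rows", 2L); cols <- get("cols", 2L)
      margin <- outer / 2 + 250
      centers <- as.matrix(expand.grid(
        x = margin + (seq_len(cols) - 1L) * pitch,
        y = margin + (seq_len(rows) - 1L) * pitch))
      ba <- c(2 * margin + (cols - 1L) * pitch,
              2 * margin + (rows - 1L) * pitch)
      mats <- materialTable(c("base", "ink"))
      ann <- lapply(seq_len(nrow(centers)), function(k)
        annulusShape(centers[k, ], inner, outer))
      PrintDesign(list(
        layerSpec(0L, get("baseThickness", 100), list(base = list()),
                  mode = "full_plane"),
        layerSpec(1L, get("thickness", 100), list(ink = ann))),
        mats, ba, projector)
    },
    core_shell = {
      cd <- get("coreDiameter", 1000)
      m <- get("shellMargin", 500)
      ct <- get("coreLayerThickness", 200)
      st <- get("shellLayerThickness", 200)
      nsl <- get("nShellLayers", 1L)
      ba <- c(cd + 2 * m, cd + 2 * m)
      mats <- materialTable(c("shell", "core"),
                            label = c("acellular shell", "cellular core"))
      shellPlane <- list(rectShape(ba / 2, ba[1], ba[2]))
      coreDisk <- diskShape(ba / 2, cd)
      coreHole <- diskShape(ba / 2, cd, negative = TRUE)
      below <- lapply(seq_len(nsl), function(i)
        layerSpec(i - 1L, st, list(shell = list()), mode = "full_plane"))
      mid <- layerSpec(nsl, ct,
                       list(core = list(coreDisk),
                            shell = c(shellPlane, list(coreHole))))
      above <- lapply(seq_len(nsl), function(i)
        layerSpec(nsl + i, st, list(shell = list()), mode = "full_plane"))
      PrintDesign(c(below, list(mid), above), mats, ba, projector)
    },
    mosaic = {
      tile <- get("tile", 1000)
      rows <- get("rows", 2L); cols <- get("cols", 2L)
      matIds <- get("materials", c("A", "B", "C", "D")[
        seq_len(min(4L, rows * cols))])
      if (length(matIds) > 4L)
        stop("mosaic with ", length(matIds),
             " materials rejected: the sled holds at most 4 bioinks")
      ba <- c(cols * tile, rows * tile)
      mats <- materialTable(matIds)
      regions <- stats::setNames(
        vector("list", length(matIds)), matIds)
      k <- 0L
      for (r in seq_len(rows)) for (cc in seq_len(cols)) {
        mid <- matIds[(k %% length(matIds)) + 1L]
        regions[[mid]] <- c(regions[[mid]], list(
          rectShape(c((cc - 0.5) * tile, (r - 0.5) * tile), tile, tile)))
        k <- k + 1L
      }
      PrintDesign(list(layerSpec(0L, get("thickness", 100), regions)),
                  mats, ba, projector)
    })
}
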
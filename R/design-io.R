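#' Read and write print designs as YAML or JSON
#'
#' Designs serialize to a plain document mirroring the [PrintDesign-class]
#' schema: `materials`, `build_area`, `projector`, and `layers` with
#' per-material shape lists. All lengths are um. Format is chosen from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param design [PrintDesign-class].
#' @param path output (input) file path.
#' @return `readDesign` returns a validated [PrintDesign-class];
#'   `writeDesign` returns `path` invisibly.
#' @export
writeDesign <- function(design, path) {
  doc <- list(
    build_area = design@buildArea,
    materials = lapply(seq_len(nrow(design@materials)), function(i)
      as.list(design@materials[i, ])),
    projector = list(
      pixel_pitch = design@projector@pixelPitch,
      resolution = design@projector@resolution,
      intensity = design@projector@intensity,
      wavelength = design@projector@wavelength),
    layers = lapply(design@layers, function(l) list(
      index = l$index, thickness = l$thickness, mode = l$mode,
      regions = lapply(l$regions, function(shapes)
        lapply(shapes, shapeToList)))))
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(doc, path)
  else
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  mats <- do.call(rbind, lapply(doc$materials, function(m)
    data.frame(id = m$id, label = m$label,
               dropletIndex = as.integer(m$dropletIndex))))
  proj <- ProjectorConfig(pixelPitch = doc$projector$pixel_pitch,
                          resolution = unlist(doc$projector$resolution),
                          intensity = doc$projector$intensity,
                          wavelength = doc$projector$wavelength %||% 405)
  layers <- lapply(doc$layers, function(l) {
    regions <- lapply(l$regions, function(shapes)
      lapply(shapes, shapeFromList))
    suppressWarnings(
      layerSpec(l$index, l$thickness, regions, mode = l$mode))
  })
  PrintDesign(layers, mats, unlist(doc$build_area), proj)
}

shapeToList <- function(sh) {
  out <- unclass(sh)
  if (!is.null(out$vertices)) {
    out$vertices <- lapply(seq_len(nrow(sh$vertices)),
                           function(i) as.numeric(sh$vertices[i, ]))
  }
  out
}

shapeFromList <- function(l) {
  neg <- isTRUE(l$negative)
  switch(l$kind,
    disk = diskShape(unlist(l$center), l$diameter, neg),
    annulus = annulusShape(unlist(l$center), l$inner, l$outer, neg),
    rect = rectShape(unlist(l$center), l$width, l$height, neg),
    polygon = polygonShape(do.call(rbind, lapply(l$vertices, unlist)), neg),
    stop("unknown shape kind in design file: ", l$kind))
}
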
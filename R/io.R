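#' Read a channel image (PNG or TIFF)
#'
#' Intensities are mapped to [0, 1] doubles; the source bit depth is
#' recorded in the `bitDepth` attribute. Multi-page TIFFs come back as a
#' list of matrices in page order; RGB(A) content is rejected — channel
#' images must be grayscale.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return a matrix (single image) or list of matrices (multi-page TIFF),
#'   values in [0, 1].
#' @export
readChannelImage <- function(path) {
  asGray <- function(m, depth) {
    if (length(dim(m)) == 3L)
      stop("color images are not supported; supply grayscale channels")
    structure(m, bitDepth = depth)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path, info = TRUE)
    info <- attr(m, "info")
    asGray(m, (info$bit.depth %||% 8L))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    pages <- lapply(pages, function(p)
      asGray(p, attr(p, "bits.per.sample") %||% 16L))
    if (length(pages) == 1L) pages[[1]] else pages
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write channels of a render (or plain matrices) to image files
#'
#' Multi-channel content goes to one 16-bit multi-page TIFF (one page per
#' channel, in channel order) or to per-channel PNGs.
#'
#' @param x a [SyntheticRender-class], a matrix, or a list of matrices with
#'   values in [0, 1].
#' @param path output path; `.tif`/`.tiff` for multi-page TIFF, `.png` for
#'   PNG (per-channel files get a `_ch<k>` suffix).
#' @return the file path(s), invisibly.
#' @export
writeChannelImage <- function(x, path) {
  chans <- if (is(x, "SyntheticRender"))
    lapply(seq_len(dim(x@image)[3]), function(k) x@image[, , k])
  else if (is.matrix(x)) list(x)
  else x
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(chans, path, bits.per.sample = 16L)
    invisible(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(chans) == 1L) {
      png::writePNG(chans[[1]], path)
      invisible(path)
    } else {
      out <- vapply(seq_along(chans), function(k) {
        fn <- sub("\\.png$", sprintf("_ch%d.png", k), path,
                  ignore.case = TRUE)
        png::writePNG(chans[[k]], fn)
        fn
      }, character(1))
      invisible(out)
    }
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Write / read a measurement table as CSV
#'
#' Numeric columns are written at full double precision so tables
#' round-trip to better than 1e-9 relative.
#'
#' @param rows data.frame.
#' @param path CSV path.
#' @return `path` / the data.frame.
#' @export
writeTable <- function(rows, path) {
  utils::write.csv(format(rows, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
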
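#' Feature shape constructors
#'
#' Shapes live in the continuous design frame (um, origin at the build-area
#' lower-left corner). A region is a list of shapes; shapes with
#' `negative = TRUE` are subtracted from the union of the positive shapes of
#' the same region, which gives exact constructive geometry for features
#' such as the open lattice (a full-plane rectangle minus hole disks).
#'
#' @param center numeric(2), shape center (x, y) in um.
#' @param diameter disk diameter (um).
#' @param negative logical; subtract this shape from the region?
#' @return A `FeatureShape` list with a `kind` field.
#' @name shapes
NULL

#' @rdname shapes
#' @export
diskShape <- function(center, diameter, negative = FALSE) {
  stopifnot(length(center) == 2L, diameter > 0)
  structure(list(kind = "disk", center = as.numeric(center),
                 diameter = as.numeric(diameter), negative = negative),
            class = "FeatureShape")
}

#' @rdname shapes
#' @param inner,outer annulus inner and outer diameters (um), inner < outer.
#' @export
annulusShape <- function(center, inner, outer, negative = FALSE) {
  stopifnot(length(center) == 2L)
  if (!(inner > 0 && outer > inner))
    stop("annulus requires 0 < inner < outer diameter")
  structure(list(kind = "annulus", center = as.numeric(center),
                 inner = as.numeric(inner), outer = as.numeric(outer),
                 negative = negative),
            class = "FeatureShape")
}

#' @rdname shapes
#' @param width,height rectangle extents (um).
#' @export
rectShape <- function(center, width, height, negative = FALSE) {
  stopifnot(length(center) == 2L, width > 0, height > 0)
  structure(list(kind = "rect", center = as.numeric(center),
                 width = as.numeric(width), height = as.numeric(height),
                 negative = negative),
            class = "FeatureShape")
}

#' @rdname shapes
#' @param vertices two-column matrix of polygon vertices (um); the polygon
#'   must be simple (non-self-intersecting).
#' @export
polygonShape <- function(vertices, negative = FALSE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (polygonSelfIntersects(vertices))
    stop("polygon must be simple (non-self-intersecting)")
  structure(list(kind = "polygon", vertices = vertices,
                 center = colMeans(vertices), negative = negative),
            class = "FeatureShape")
}

# Disk whose radius is modulated by a small sum of harmonics; used by the
# synthetic renderer to emulate boundary roughness of printed features.
roughDiskShape <- function(center, diameter, amplitude, harmonics, phases,
                           negative = FALSE) {
  structure(list(kind = "rough_disk", center = as.numeric(center),
                 diameter = as.numeric(diameter),
                 amplitude = amplitude, harmonics = harmonics,
                 phases = phases, negative = negative),
            class = "FeatureShape")
}

# Segment-intersection test over all non-adjacent edge pairs; adequate for
# the handful of vertices a design polygon carries.
polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

# Axis-aligned bounding box (xmin, ymin, xmax, ymax) in um.
shapeBBox <- function(sh) {
  switch(sh$kind,
    disk = c(sh$center - sh$diameter / 2, sh$center + sh$diameter / 2),
    rough_disk = {
      r <- sh$diameter / 2 + sh$amplitude
      c(sh$center - r, sh$center + r)
    },
    annulus = c(sh$center - sh$outer / 2, sh$center + sh$outer / 2),
    rect = c(sh$center[1] - sh$width / 2, sh$center[2] - sh$height / 2,
             sh$center[1] + sh$width / 2, sh$center[2] + sh$height / 2),
    polygon = c(min(sh$vertices[, 1]), min(sh$vertices[, 2]),
                max(sh$vertices[, 1]), max(sh$vertices[, 2])),
    stop("unknown shape kind: ", sh$kind)
  )
}

# Vectorized membership test of the grid outer(ys, xs) in one shape.
# Returns a logical matrix of dim (length(ys), length(xs)).
gridInShape <- function(sh, xs, ys) {
  switch(sh$kind,
    disk = {
      r2 <- (sh$diameter / 2)^2
      outer((ys - sh$center[2])^2, (xs - sh$center[1])^2, "+") <= r2
    },
    rough_disk = {
      dx <- outer(rep(1, length(ys)), xs - sh$center[1])
      dy <- outer(ys - sh$center[2], rep(1, length(xs)))
      th <- atan2(dy, dx)
      r <- sh$diameter / 2
      for (k in seq_along(sh$harmonics))
        r <- r + sh$amplitude / length(sh$harmonics) *
          cos(sh$harmonics[k] * th + sh$phases[k])
      dx * dx + dy * dy <= r * r
    },
    annulus = {
      d2 <- outer((ys - sh$center[2])^2, (xs - sh$center[1])^2, "+")
      d2 <= (sh$outer / 2)^2 & d2 >= (sh$inner / 2)^2
    },
    rect = {
      inx <- abs(xs - sh$center[1]) <= sh$width / 2
      iny <- abs(ys - sh$center[2]) <= sh$height / 2
      outer(iny, inx, "&")
    },
    polygon = {
      g <- expand.grid(y = ys, x = xs)
      matrix(pracma::inpolygon(g$x, g$y,
                               sh$vertices[, 1], sh$vertices[, 2],
                               boundary = TRUE),
             nrow = length(ys))
    },
    stop("unknown shape kind: ", sh$kind)
  )
}

#' Coverage rasterization of a shape region
#'
#' Computes, for every pixel of an `nrow x ncol` raster with pixel pitch
#' `pitch` (um), the fraction of `supersample^2` sub-pixel sample points
#' (placed at sub-pixel centers) that fall inside the union of the positive
#' shapes minus the union of the negative shapes. Pixel (i, j) (1-based)
#' covers x in [(j-1) pitch, j pitch], y in [(i-1) pitch, i pitch]; its
#' center sits at ((j - 0.5) pitch, (i - 0.5) pitch).
#'
#' @param shapes list of `FeatureShape`s.
#' @param nrow,ncol raster dimensions (pixels).
#' @param pitch um per pixel.
#' @param supersample sub-samples per pixel edge (>= 1).
#' @return numeric matrix of covered fractions in [0, 1].
#' @keywords internal
coverageMatrix <- function(shapes, nrow, ncol, pitch, supersample = 4L) {
  ss <- as.integer(supersample)
  stopifnot(ss >= 1L)
  nr <- nrow * ss
  nc <- ncol * ss
  sub <- pitch / ss
  pos <- matrix(FALSE, nr, nc)
  hasNeg <- any(vapply(shapes, function(s) isTRUE(s$negative), logical(1)))
  neg <- if (hasNeg) matrix(FALSE, nr, nc) else NULL
  xs_all <- (seq_len(nc) - 0.5) * sub
  ys_all <- (seq_len(nr) - 0.5) * sub
  for (sh in shapes) {
    bb <- shapeBBox(sh)
    jr <- which(xs_all >= bb[1] - sub & xs_all <= bb[3] + sub)
    ir <- which(ys_all >= bb[2] - sub & ys_all <= bb[4] + sub)
    if (!length(jr) || !length(ir)) next
    m <- gridInShape(sh, xs_all[jr], ys_all[ir])
    if (isTRUE(sh$negative)) neg[ir, jr] <- neg[ir, jr] | m
    else pos[ir, jr] <- pos[ir, jr] | m
  }
  if (hasNeg) pos <- pos & !neg
  blockMean(pos, ss)
}

# Mean over ss x ss blocks; (nr*ss, nc*ss) -> (nr, nc).
blockMean <- function(m, ss) {
  if (ss == 1L) return(m + 0)
  nr <- nrow(m) %/% ss
  nc <- ncol(m) %/% ss
  t1 <- rowsum(m + 0, rep(seq_len(nr), each = ss), reorder = FALSE)
  t2 <- t(rowsum(t(t1), rep(seq_len(nc), each = ss), reorder = FALSE))
  unname(t2) / (ss * ss)
}
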
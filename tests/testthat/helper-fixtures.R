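# Shared fixtures and independent oracles used across the suite.

# O(n^2) all-pairs minimum distance, written as an explicit double loop so
# it stays independent of the package's dist()-based implementation.
bruteForceMinPairDist <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# Per-point nearest-neighbor distances by the same explicit enumeration.
bruteForceNND <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Dense point-sampling estimate of a disk's area on a fine independent grid.
bruteForceDiskArea <- function(diameter, step = 1) {
  r <- diameter / 2
  xs <- seq(-r - step, r + step, by = step)
  inside <- outer(xs^2, xs^2, "+") <= r^2
  sum(inside) * step^2
}

# Binary digital disk mask: pixel centers at (i - 0.5, j - 0.5) * pixelSize.
digitalDisk <- function(diameter, pixelSize, pad = 4L) {
  r <- diameter / 2 / pixelSize
  n <- ceiling(2 * r) + 2L * pad
  ctr <- n / 2
  xs <- seq_len(n) - 0.5
  outer((xs - ctr)^2, (xs - ctr)^2, "+") <= r^2
}

# Small multi-material design with randomized layer/material structure,
# used by the schedule property tests. Materials get disjoint disk regions
# on a coarse grid so co-planar purity holds by construction.
randomDesign <- function(nMaterials = NULL, nLayers = NULL) {
  nMaterials <- nMaterials %||% sample(2:4, 1)
  nLayers <- nLayers %||% sample(2:4, 1)
  ids <- paste0("m", seq_len(nMaterials))
  mats <- materialTable(ids)
  slots <- as.matrix(expand.grid(x = c(500, 1500, 2500, 3500),
                                 y = c(500, 1500)))
  layers <- lapply(seq_len(nLayers), function(k) {
    present <- sort(sample(seq_len(nMaterials),
                           sample(seq_len(min(3, nMaterials)), 1)))
    take <- sample(nrow(slots), length(present))
    regions <- stats::setNames(lapply(seq_along(present), function(i)
      list(diskShape(slots[take[i], ], 400))), ids[present])
    layerSpec(k - 1L, sample(c(200, 300), 1), regions)
  })
  PrintDesign(layers, mats, c(4000, 2000),
              projector = ProjectorConfig(pixelPitch = 50,
                                          resolution = c(80L, 40L)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
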
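# Small projector covering a 2000 x 2000 um field at 10 um/px.
tinyProjector <- function(pitch = 10, n = 200L)
  ProjectorConfig(pixelPitch = pitch, resolution = c(n, n))

oneDiskDesign <- function(diameter = 500, pitch = 10, n = 200L) {
  PrintDesign(list(layerSpec(0L, 100, list(
    ink = list(diskShape(c(n * pitch / 2, n * pitch / 2), diameter))))),
    materialTable("ink"), c(n * pitch, n * pitch),
    projector = tinyProjector(pitch, n))
}

test_that("empty region rasterizes to an all-zero mask", {
  d <- oneDiskDesign()
  d@layers[[1]]$regions$ink <- list()
  m <- rasterizeLayer(d@layers[[1]], "ink", d)
  expect_true(all(m@raster == 0L))
  expect_equal(dim(m@raster), c(200L, 200L))
})

test_that("rasterized disk area matches the analytic and sampled oracles", {
  d <- oneDiskDesign(diameter = 500, pitch = 10)
  m <- rasterizeLayer(d@layers[[1]], "ink", d, supersample = 4L)
  rasterArea <- sum(m@raster) / 255 * 10^2
  analytic <- pi * 250^2
  expect_lt(abs(rasterArea - analytic) / analytic, 0.005)
  sampled <- bruteForceDiskArea(500, step = 1)
  expect_lt(abs(rasterArea - sampled) / sampled, 0.005)
})

test_that("a 500 um disk spans 10 pixels across its equator at 50 um/px", {
  d <- oneDiskDesign(diameter = 500, pitch = 50, n = 40L)
  m <- rasterizeLayer(d@layers[[1]], "ink", d)
  eq <- m@raster[which.max(rowSums(m@raster)), ]
  expect_equal(sum(eq > 127), 10L)
})

test_that("rasterization is translation-equivariant to whole-pixel shifts", {
  pitch <- 10
  base <- oneDiskDesign(diameter = 330, pitch = pitch)
  m0 <- rasterizeLayer(base@layers[[1]], "ink", base)
  shifted <- base
  shifted@layers[[1]]$regions$ink[[1]]$center <-
    shifted@layers[[1]]$regions$ink[[1]]$center + c(3, 5) * pitch
  m1 <- rasterizeLayer(shifted@layers[[1]], "ink", shifted)
  expect_identical(m1@raster[(1 + 5):200, (1 + 3):200],
                   m0@raster[1:(200 - 5), 1:(200 - 3)])
})

test_that("disk coverage converges to the analytic area as pitch shrinks", {
  # d / pitch = 50 here; the relative error bound is 1%
  d <- oneDiskDesign(diameter = 500, pitch = 10)
  m <- rasterizeLayer(d@layers[[1]], "ink", d, supersample = 4L)
  expect_lt(abs(sum(m@raster) / 255 * 100 - pi * 250^2) / (pi * 250^2),
            0.01)
})

test_that("mask stack enumerates nonempty (layer, material) pairs in order", {
  # base-plus-two-tracers print: 3 base layers of A, feature layer with B, C
  mats <- materialTable(c("A", "B", "C"))
  layers <- c(
    lapply(0:2, function(i)
      layerSpec(i, 100, list(A = list()), mode = "full_plane")),
    list(layerSpec(3L, 100, list(
      B = list(diskShape(c(500, 500), 300)),
      C = list(diskShape(c(1500, 500), 300))))))
  d <- PrintDesign(layers, mats, c(2000, 1000),
                   projector = ProjectorConfig(pixelPitch = 50,
                                               resolution = c(40L, 20L)))
  st <- buildMaskStack(d)
  expect_length(masks(st), 5L)
  expect_equal(vapply(masks(st), function(m) m@material, character(1)),
               c("A", "A", "A", "B", "C"))
  expect_equal(vapply(masks(st), function(m) m@layerIndex, integer(1)),
               c(0L, 1L, 2L, 3L, 3L))
})

test_that("single-material single-layer design yields one mask", {
  d <- oneDiskDesign()
  st <- buildMaskStack(d)
  expect_length(masks(st), 1L)
})

test_that("checkerboard post and lattice masks are exactly complementary", {
  proj <- ProjectorConfig(pixelPitch = 50, resolution = c(70L, 55L))
  d <- makeCheckerboardDesign(rows = 2L, cols = 2L, projector = proj)
  st <- buildMaskStack(d, supersample = 4L)
  mm <- masks(st)
  post <- mm[[which(vapply(mm, function(m) m@material, character(1)) ==
                      "post")]]
  latt <- mm[[which(vapply(mm, function(m) m@material, character(1)) ==
                      "lattice")]]
  pf <- post@raster / 255
  lf <- latt@raster / 255
  # disjoint: no pixel belongs to both thresholded masks (exact half
  # coverage, value 128, marks the shared nesting boundary), and coverage
  # never sums past full exposure
  expect_identical(sum(post@raster > 128L & latt@raster > 128L), 0L)
  expect_lte(max(pf + lf), 1 + 1 / 255 + 1e-12)
  # complementary inside the build area, zero outside
  xs <- (seq_len(ncol(pf)) - 0.5) * 50
  ys <- (seq_len(nrow(pf)) - 0.5) * 50
  inside <- outer(ys < d@buildArea[2] - 25, xs < d@buildArea[1] - 25, "&")
  tot <- pf + lf
  expect_true(all(abs(tot[inside] - 1) <= 1 / 255 + 1e-12))
  outside <- outer(ys > d@buildArea[2] + 25, xs > d@buildArea[1] + 25, "|")
  expect_true(all(tot[outside] == 0))
})

test_that("shapes outside the build area are rejected by name", {
  d <- oneDiskDesign()
  d@layers[[1]]$regions$ink[[1]]$center <- c(1990, 1000)
  expect_error(rasterizeLayer(d@layers[[1]], "ink", d), "disk")
})

test_that("overlapping co-planar materials abort the mask stack", {
  mats <- materialTable(c("a", "b"))
  d <- PrintDesign(list(layerSpec(0L, 100, list(
    a = list(diskShape(c(500, 500), 400)),
    b = list(diskShape(c(600, 500), 400))))),
    mats, c(2000, 1000),
    projector = ProjectorConfig(pixelPitch = 50,
                                resolution = c(40L, 20L)))
  expect_error(buildMaskStack(d), "overlap")
})

test_that("designs round-trip through YAML and JSON files", {
  d <- makeCheckerboardDesign(rows = 2L, cols = 3L)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeDesign(d, f)
    d2 <- readDesign(f)
    expect_equal(d2@buildArea, d@buildArea)
    expect_equal(d2@materials, d@materials)
    expect_length(d2@layers, length(d@layers))
    st1 <- buildMaskStack(d, supersample = 2L)
    st2 <- buildMaskStack(d2, supersample = 2L)
    expect_identical(masks(st2)[[2]]@raster, masks(st1)[[2]]@raster)
  }
})

test_that("mask PNG export writes one file per mask plus a manifest", {
  dir <- withr::local_tempdir()
  d <- makeCheckerboardDesign(rows = 2L, cols = 2L,
    projector = ProjectorConfig(pixelPitch = 50,
                                resolution = c(70L, 55L)))
  st <- buildMaskStack(d, supersample = 2L)
  writeMaskStack(st, dir)
  files <- list.files(dir)
  expect_setequal(files, c("layer000_mat0.png", "layer001_mat1.png",
                           "layer001_mat2.png", "manifest.json"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$pixelPitch, 50)
  # round-trip: file content = raster (flipped vertically), 8-bit
  img <- png::readPNG(file.path(dir, "layer001_mat1.png"))
  m <- masks(st)[[2]]@raster
  expect_equal(round(img * 255)[nrow(m):1, ], m, ignore_attr = TRUE)
})
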
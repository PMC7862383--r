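test_that("dose model reproduces the cellular-print calibration", {
  expect_identical(exposureTime(200, 10), 60)
  expect_identical(exposureTime(300, 10), 120)
  # constant dose: doubling irradiance halves the time
  expect_identical(exposureTime(200, 20), 30)
  expect_identical(exposureTime(300, 5), 240)
  # linear interpolation between the tabulated points
  expect_equal(exposureTime(250, 10), 90)
})

test_that("unknown thickness without interpolation names the known keys", {
  m <- defaultDoseModel(interpolate = FALSE)
  expect_error(exposureTime(250, 10, m), "200, 300")
  expect_warning(exposureTime(100, 10), "clamped")
})

methodsExampleDesign <- function() {
  mats <- materialTable(c("A", "B", "C"))
  layers <- c(
    lapply(0:2, function(i)
      layerSpec(i, 200, list(A = list()), mode = "full_plane")),
    list(layerSpec(3L, 200, list(
      B = list(diskShape(c(500, 500), 300)),
      C = list(diskShape(c(1500, 500), 300))))))
  PrintDesign(layers, mats, c(2000, 1000),
              projector = ProjectorConfig(pixelPitch = 50,
                                          resolution = c(40L, 20L),
                                          intensity = 10))
}

test_that("base-plus-two-tracers print compiles to the expected sequence", {
  d <- methodsExampleDesign()
  st <- buildMaskStack(d, supersample = 2L)
  s <- compileSchedule(d, st, rinsePolicy = "strict")
  ev <- events(s)
  expect_identical(sum(ev$kind == "EXPOSE"), 5L)
  expect_identical(ev$kind[1], "LOWER")
  # strict policy: rinse precedes both the A->B and the B->C exposure
  expect_identical(sum(ev$kind == "RINSE"), 2L)
  expect_identical(sum(ev$kind == "WICK"), 2L)
  expect_identical(nrow(validateSchedule(s)), 0L)

  # narrative policy: leaving the dye-free base droplet is not rinsed
  s2 <- compileSchedule(d, st, rinsePolicy = "as_described")
  expect_identical(sum(events(s2)$kind == "RINSE"), 1L)
  rinseAt <- which(events(s2)$kind == "RINSE")
  expB <- which(events(s2)$kind == "EXPOSE" & events(s2)$material == "B")
  expC <- which(events(s2)$kind == "EXPOSE" & events(s2)$material == "C")
  expect_true(rinseAt > expB && rinseAt < expC)
})

test_that("single-material prints need no rinse or sled travel", {
  mats <- materialTable("A")
  d <- PrintDesign(lapply(0:2, function(i)
    layerSpec(i, 200, list(A = list()), mode = "full_plane")),
    mats, c(2000, 1000),
    projector = ProjectorConfig(pixelPitch = 50, resolution = c(40L, 20L),
                                intensity = 10))
  s <- compileSchedule(d, buildMaskStack(d, supersample = 2L))
  ev <- events(s)
  expect_identical(sum(ev$kind == "EXPOSE"), 3L)
  expect_identical(sum(ev$kind == "RINSE"), 0L)
  expect_identical(sum(ev$kind == "SLED_MOVE"), 0L)
})

test_that("exposure Z accumulates layer thicknesses above the 50 um gap", {
  d <- methodsExampleDesign()
  s <- compileSchedule(d, buildMaskStack(d, supersample = 2L))
  ev <- events(s)
  z <- ev$z[ev$kind == "EXPOSE"]
  expect_equal(z, 50 + c(0, 200, 400, 600, 600))
  # co-planar materials of layer 3 expose at the same height
  expect_equal(z[4], z[5])
})

test_that("validation flags mutated schedules precisely", {
  d <- methodsExampleDesign()
  s <- compileSchedule(d, buildMaskStack(d, supersample = 2L))
  # delete one rinse -> exactly one violation naming the offending exposure
  mut <- s
  rinseIdx <- which(mut@events$kind == "RINSE")[1]
  mut@events <- mut@events[-rinseIdx, ]
  v <- validateSchedule(mut)
  expect_identical(nrow(v), 1L)
  expect_identical(v$code, "missing_rinse")
  expect_match(v$message, "A -> B")

  # five materials in the event stream violate the sled capacity
  mut2 <- s
  extra <- mut2@events[mut2@events$kind == "EXPOSE", ][1:2, ]
  extra$material <- c("D", "E")
  mut2@events <- rbind(mut2@events, extra)
  v2 <- validateSchedule(mut2)
  expect_true(any(v2$code == "material_limit"))
  expect_match(v2$message[v2$code == "material_limit"], "5 > 4")

  # first event must be a LOWER
  mut3 <- s
  mut3@events <- mut3@events[-1, ]
  expect_true("first_event" %in% validateSchedule(mut3)$code)
})

test_that("compiled schedules validate cleanly over randomized designs", {
  withr::local_seed(42)
  for (i in 1:25) {
    d <- randomDesign()
    st <- buildMaskStack(d, supersample = 2L)
    s <- compileSchedule(d, st)
    expect_identical(nrow(validateSchedule(s)), 0L)
    ev <- events(s)
    expect_identical(sum(ev$kind == "EXPOSE"), length(masks(st)))
    # strict policy: every material change interleaves RINSE + WICK
    expIdx <- which(ev$kind == "EXPOSE")
    mats <- ev$material[expIdx]
    if (length(expIdx) > 1L) for (k in 2:length(expIdx)) {
      if (mats[k] != mats[k - 1L]) {
        between <- ev$kind[(expIdx[k - 1L] + 1L):(expIdx[k] - 1L)]
        expect_true(all(c("RINSE", "WICK") %in% between))
      }
    }
  }
})

test_that("duration estimate is additive and linear in exposure time", {
  d <- methodsExampleDesign()
  s <- compileSchedule(d, buildMaskStack(d, supersample = 2L))
  t1 <- estimateDuration(s)
  s2 <- s
  s2@events$duration[s2@events$kind == "EXPOSE"] <-
    2 * s2@events$duration[s2@events$kind == "EXPOSE"]
  t2 <- estimateDuration(s2)
  totalExposure <- sum(s@events$duration[s@events$kind == "EXPOSE"])
  expect_equal(t2 - t1, totalExposure)
  # a lone 60 s exposure with no motion = 60 s plus nothing else
  lone <- s
  lone@events <- data.frame(kind = "EXPOSE", z = 50, material = "A",
                            maskIndex = 1L, sledTarget = NA_integer_,
                            duration = 60, layer = 0L, volume = NA_real_,
                            note = "")
  expect_equal(estimateDuration(lone), 60)
})

test_that("a two-material checkerboard print fits the 15-minute envelope", {
  proj <- ProjectorConfig(pixelPitch = 50, resolution = c(110L, 90L),
                          intensity = 10)
  d <- makeCheckerboardDesign(rows = 3L, cols = 3L, projector = proj)
  st <- buildMaskStack(d, supersample = 2L)
  s <- suppressWarnings(compileSchedule(d, st))
  expect_lte(estimateDuration(s), 900)
  # exceeding the soft bound warns instead of failing
  slow <- s
  slow@events$duration[slow@events$kind == "EXPOSE"] <- 1000
  expect_warning(estimateDuration(slow), "envelope")
})

test_that("schedule JSON export preserves the event sequence", {
  d <- methodsExampleDesign()
  s <- compileSchedule(d, buildMaskStack(d, supersample = 2L))
  f <- withr::local_tempfile(fileext = ".json")
  writeSchedule(s, f)
  doc <- jsonlite::read_json(f)
  expect_identical(length(doc$events), nrow(events(s)))
  expect_identical(doc$rinse_policy, "strict")
  kinds <- vapply(doc$events, function(e) e$kind, character(1))
  expect_identical(kinds, events(s)$kind)
  expect_true(file.exists(sub("\\.json$", ".log", f)))
})
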
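#' Compile a print design into a machine-event schedule
#'
#' Walks the mask stack in print order and emits the event sequence the
#' instrument executes: an initial LOWER of the build plate into the first
#' bioink droplet, an EXPOSE per mask at the correct cumulative Z, RAISE
#' steps between layers, and — at material switches — a clearance RAISE,
#' sled travel and (policy-dependent) a saline RINSE followed by a WICK of
#' residual fluid before lowering into the next droplet.
#'
#' Exposure Z for layer k is `firstLayerOffset + sum(thickness of layers
#' 0..k-1)`: the plate first closes a thin 50 um gap against the sled, then
#' steps up by one layer thickness per layer. Co-planar materials of one
#' layer expose at the same Z.
#'
#' Under `rinsePolicy = "strict"` every material switch is rinsed. Under
#' `"as_described"` the switch out of the dye-free far-left droplet
#' (droplet index 0) is not rinsed, reproducing the narrative print
#' protocol for a base-plus-two-tracers structure.
#'
#' @param design [PrintDesign-class].
#' @param masks [MaskStack-class] built from `design`.
#' @param model [DoseModel-class] used for exposure durations.
#' @param rinsePolicy "strict" or "as_described".
#' @param firstLayerOffset initial plate-sled gap (um, default 50).
#' @param clearanceLift Z lift above the current layer during sled travel
#'   (um).
#' @param rinseVolume saline volume per rinse (mL; the protocol uses
#'   2-5 mL).
#' @return a [PrintSchedule-class].
#' @export
compileSchedule <- function(design, masks, model = defaultDoseModel(),
                            rinsePolicy = c("strict", "as_described"),
                            firstLayerOffset = 50, clearanceLift = 2000,
                            rinseVolume = 3.5) {
  rinsePolicy <- match.arg(rinsePolicy)
  thick <- vapply(design@layers, function(l) l$thickness, numeric(1))
  zExpose <- firstLayerOffset + c(0, cumsum(thick))[seq_along(thick)]
  drop <- stats::setNames(design@materials$dropletIndex,
                          design@materials$id)
  ev <- list()
  add <- function(kind, z = NA_real_, material = NA_character_,
                  maskIndex = NA_integer_, sledTarget = NA_integer_,
                  duration = NA_real_, layer = NA_integer_,
                  volume = NA_real_, note = "") {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, z = z, material = material, maskIndex = maskIndex,
      sledTarget = sledTarget, duration = duration, layer = layer,
      volume = volume, note = note, stringsAsFactors = FALSE)
  }
  curMat <- NULL
  curZ <- NA_real_
  for (k in seq_along(masks@masks)) {
    m <- masks@masks[[k]]
    if (!m@material %in% names(drop))
      stop("mask material '", m@material, "' has no sled droplet position")
    li <- m@layerIndex + 1L
    z <- zExpose[li]
    dur <- exposureTime(thick[li], design@projector@intensity, model)
    if (is.null(curMat)) {
      add("LOWER", z = z, material = m@material,
          sledTarget = drop[[m@material]],
          note = "lower build plate into first droplet")
    } else if (identical(curMat, m@material)) {
      if (z > curZ + 1e-9)
        add("RAISE", z = z, material = m@material,
            note = "step up one layer height")
    } else {
      add("RAISE", z = curZ + clearanceLift, material = curMat,
          note = "lift clear of droplet for sled travel")
      doRinse <- rinsePolicy == "strict" || drop[[curMat]] > 0L
      if (doRinse) {
        add("SLED_MOVE", sledTarget = -1L, note = "to rinse station")
        add("RINSE", volume = rinseVolume,
            note = "flush structure with saline")
        add("WICK", note = "wick residual saline from build plate")
      }
      add("SLED_MOVE", sledTarget = drop[[m@material]],
          material = m@material, note = "to next bioink droplet")
      add("LOWER", z = z, material = m@material,
          sledTarget = drop[[m@material]],
          note = "lower into droplet at layer height")
    }
    add("EXPOSE", z = z, material = m@material, maskIndex = k,
        duration = dur, layer = m@layerIndex)
    curMat <- m@material
    curZ <- z
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  new("PrintSchedule", events = events, design = design,
      rinsePolicy = rinsePolicy)
}

#' Validate a print schedule
#'
#' Checks the structural invariants of a schedule and returns violations as
#' data, not exceptions: (a) at most 4 materials are exposed (the sled
#' limit); (b) under strict rinse policy every material switch carries a
#' RINSE and a WICK between the two exposures; (c) exposures of the same
#' layer share one Z; (d) exposure Z is non-decreasing across layers;
#' (e) the first event is a LOWER.
#'
#' @param s [PrintSchedule-class].
#' @return data.frame with columns `code`, `message`, `eventIndex`; zero
#'   rows when the schedule is valid.
#' @export
validateSchedule <- function(s) {
  ev <- s@events
  v <- list()
  flag <- function(code, message, eventIndex = NA_integer_)
    v[[length(v) + 1L]] <<- data.frame(code = code, message = message,
                                       eventIndex = eventIndex,
                                       stringsAsFactors = FALSE)
  exp_i <- which(ev$kind == "EXPOSE")
  mats <- unique(ev$material[exp_i])
  if (length(mats) > 4L)
    flag("material_limit",
         sprintf("material count %d > 4: the sled holds at most 4 bioinks",
                 length(mats)))
  if (s@rinsePolicy == "strict" && length(exp_i) > 1L) {
    for (k in 2:length(exp_i)) {
      a <- exp_i[k - 1L]; b <- exp_i[k]
      if (!identical(ev$material[a], ev$material[b])) {
        between <- ev$kind[(a + 1L):(b - 1L)]
        if (!("RINSE" %in% between && "WICK" %in% between))
          flag("missing_rinse",
               sprintf(
                 "EXPOSE %d (%s -> %s) lacks a RINSE+WICK since EXPOSE %d",
                 b, ev$material[a], ev$material[b], a),
               b)
      }
    }
  }
  byLayer <- split(exp_i, ev$layer[exp_i])
  for (li in names(byLayer)) {
    zs <- ev$z[byLayer[[li]]]
    if (length(zs) > 1L && diff(range(zs)) > 1e-9)
      flag("coplanar_z",
           sprintf("layer %s exposures at differing Z", li),
           byLayer[[li]][1])
  }
  o <- order(ev$layer[exp_i])
  if (length(exp_i) > 1L && any(diff(ev$z[exp_i][o]) < -1e-9))
    flag("z_monotone", "exposure Z decreases across layers")
  if (nrow(ev) && ev$kind[1] != "LOWER")
    flag("first_event", "first event must be LOWER", 1L)
  out <- if (length(v)) do.call(rbind, v)
         else data.frame(code = character(), message = character(),
                         eventIndex = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate total print duration
#'
#' Sums exposure durations, axis travel times (distance / rate) and fixed
#' rinse/wick overheads over a schedule. The instrument's axis speeds are
#' not part of the calibration, so rates are plain parameters with
#' documented defaults. Totals above `softBound` (default 15 min) raise a
#' warning — the workflow is designed to finish inside that envelope.
#'
#' @param s [PrintSchedule-class].
#' @param zRate build-plate speed (um/s).
#' @param xRate sled speed (mm/s).
#' @param sledSpacing droplet spacing on the sled (mm, >= 25); the rinse
#'   station sits one spacing left of droplet 0.
#' @param rinseOverhead,wickOverhead fixed times (s) per RINSE / WICK.
#' @param softBound soft total-time bound (s); exceeding it warns.
#' @return total estimated duration in seconds.
#' @export
estimateDuration <- function(s, zRate = 500, xRate = 10, sledSpacing = 25,
                             rinseOverhead = 30, wickOverhead = 15,
                             softBound = 900) {
  stopifnot(zRate > 0, xRate > 0, sledSpacing >= 25)
  ev <- s@events
  total <- sum(ev$duration[ev$kind == "EXPOSE"], na.rm = TRUE)
  curZ <- 0
  curX <- if (nrow(ev)) (ev$sledTarget[1] %||% 0) else 0
  if (is.na(curX)) curX <- 0
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k %in% c("LOWER", "RAISE") && !is.na(ev$z[i])) {
      total <- total + abs(ev$z[i] - curZ) / zRate
      curZ <- ev$z[i]
    } else if (k == "SLED_MOVE" && !is.na(ev$sledTarget[i])) {
      total <- total + abs(ev$sledTarget[i] - curX) * sledSpacing / xRate
      curX <- ev$sledTarget[i]
    } else if (k == "RINSE") {
      total <- total + rinseOverhead
    } else if (k == "WICK") {
      total <- total + wickOverhead
    }
  }
  if (total > softBound)
    warning(sprintf(
      "estimated print time %.0f s exceeds the %d s target envelope",
      total, softBound))
  total
}

#' Export a schedule as JSON and a human-readable log
#'
#' @param s [PrintSchedule-class].
#' @param path output `.json` path; a sibling `.log` text file is written
#'   alongside when `log = TRUE`.
#' @param log also write the text log?
#' @return `path`, invisibly.
#' @export
writeSchedule <- function(s, path, log = TRUE) {
  doc <- list(rinse_policy = s@rinsePolicy,
              events = lapply(seq_len(nrow(s@events)), function(i) {
                e <- as.list(s@events[i, ])
                e[!vapply(e, function(x) is.na(x) || identical(x, ""),
                          logical(1))]
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (log) {
    lines <- vapply(seq_len(nrow(s@events)), function(i) {
      e <- s@events[i, ]
      sprintf("%3d %-10s z=%-8s mat=%-8s %s", i, e$kind,
              ifelse(is.na(e$z), "-", sprintf("%.0f", e$z)),
              ifelse(is.na(e$material), "-", e$material), e$note)
    }, character(1))
    writeLines(lines, sub("\\.json$", ".log", path))
  }
  invisible(path)
}
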
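#' Write / read a surface sequence
#'
#' The frame stack goes to a multi-page 32-bit float TIFF (one page per
#' frame; temperatures are affinely mapped into \[0, 1\] as the TIFF
#' library requires, with the mapping recorded in the JSON sidecar), the
#' per-frame summary to a CSV (`frame`, `time`, `meanT`), and timing,
#' pitch and the temperature mapping to a JSON sidecar.  The round trip
#' is lossless within float32.
#'
#' @param seq a [SurfaceSequence-class].
#' @param tiffPath,csvPath,jsonPath output paths; the CSV and JSON paths
#'   default to the TIFF path with the extension swapped.
#' @return `writeSurfaceSequence`: the TIFF path, invisibly;
#'   `readSurfaceSequence`: a [SurfaceSequence-class].
#' @export
writeSurfaceSequence <- function(seq, tiffPath,
                                 csvPath = sub("\\.tiff?$", ".csv", tiffPath),
                                 jsonPath = sub("\\.tiff?$", ".json", tiffPath)) {
  stopifnot(is(seq, "SurfaceSequence"))
  lo <- min(seq@frames); hi <- max(seq@frames)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(nFrames(seq)),
                  function(i) (seq@frames[, , i] - lo) / span)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L, reduce = FALSE)
  a <- averageSurfaceTemperature(seq)
  utils::write.csv(data.frame(frame = seq_along(a$time), time = a$time,
                              meanT = a$meanT),
                   csvPath, row.names = FALSE)
  jsonlite::write_json(list(times = seq@times, tmin = lo, tspan = span,
                            pitch = seq@meta$pitch),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(tiffPath)
}

#' @rdname writeSurfaceSequence
#' @export
readSurfaceSequence <- function(tiffPath,
                                jsonPath = sub("\\.tiff?$", ".json", tiffPath)) {
  side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiffPath, all = TRUE, as.is = FALSE)
  frames <- array(NA_real_, c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages))
    frames[, , i] <- pages[[i]] * side$tspan + side$tmin
  new("SurfaceSequence", frames = frames, times = as.numeric(side$times),
      meta = list(pitch = side$pitch))
}

#' Write a binary mask or composite image as PNG
#'
#' Masks are written 1-bit-style (0/1 grey); composites keep their
#' 10%/90% grey levels as 8-bit.
#'
#' @param m logical or numeric matrix with values in \[0, 1\].
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
writeMaskPng <- function(m, path) {
  png::writePNG(t(m * 1), path)   # transpose: image rows = y, columns = x
  invisible(path)
}

#' Write detected coordinates as a CSV list
#'
#' @param det a [DetectionResult-class] or two-column coordinate matrix.
#' @param path output CSV.
#' @return The path, invisibly.
#' @export
writeDetectionCsv <- function(det, path) {
  coords <- if (is(det, "DetectionResult")) det@coords else det
  utils::write.csv(as.data.frame(coords), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature matrix as CSV
#'
#' Feature columns are headed by their sampling timestamps (`t<seconds>`)
#' and label columns by their names; the round trip restores both.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path CSV path.
#' @return `writeFeatureMatrix`: the path, invisibly;
#'   `readFeatureMatrix`: a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  d <- as.data.frame(fm@features)
  names(d) <- paste0("t", fm@times)
  utils::write.csv(cbind(d, fm@labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  isFeat <- grepl("^t[0-9.]+$", names(d))
  if (!any(isFeat)) stop(sprintf("'%s' has no feature columns (t<seconds>)", path))
  new("FeatureMatrix", features = as.matrix(d[isFeat]),
      labels = d[, !isFeat, drop = FALSE],
      times = as.numeric(sub("^t", "", names(d)[isFeat])),
      meta = list(source = path))
}

#' Read a scenario configuration
#'
#' YAML with a `scenario` name, an optional `seed` and `outdir`, and
#' optional nested `geometry`, `simulation`, `model` and `noise`
#' sections.  Unknown top-level or section keys are rejected so that
#' typos never silently fall back to defaults.
#'
#' @param path YAML file.
#' @return Named list (validated).
#' @export
readScenarioConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("scenario", "seed", "outdir", "geometry", "simulation",
             "model", "noise")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")))
  scn <- c("rsa-9depth", "rsa-sweep", "bubble-grid", "bubble-validate",
           "noise-battery")
  if (is.null(cfg$scenario) || !cfg$scenario %in% scn)
    stop(sprintf("scenario must be one of %s", paste(scn, collapse = ", ")))
  secKeys <- list(
    geometry  = c("pitch", "coverThickness", "depths", "bubblePitch"),
    simulation = c("flux", "heatDuration", "totalDuration", "h", "emissivity",
                   "method", "dt", "frameInterval"),
    model     = c("hiddenRange", "folds", "split", "maxit", "decay"),
    noise     = c("ratios", "sds", "kind"))
  for (s in names(secKeys)) {
    bad <- setdiff(names(cfg[[s]]), secKeys[[s]])
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", s, paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run an end-to-end scenario
#'
#' Executes one of the study scenarios at the configured scale and
#' writes an artifact bundle (TIFF stacks, CSV tables, PNG masks) plus a
#' `manifest.json` listing every file with its MD5 checksum; the fully
#' resolved configuration is archived alongside.  Deterministic for a
#' fixed seed.
#'
#' @param config list from [readScenarioConfig()] (or of the same shape).
#' @param outdir output directory (default from the config, else a
#'   tempdir subdirectory).
#' @return The manifest as a list, invisibly.
#' @export
runScenario <- function(config, outdir = NULL) {
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) outdir <- file.path(tempdir(), config$scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  geo <- config$geometry
  simArgs <- config$simulation
  seed <- as.integer(config$seed)
  files <- character()

  put <- function(p) { files <<- c(files, p); p }

  if (config$scenario == "rsa-9depth") {
    depths <- geo$depths
    if (is.null(depths)) depths <- c(1, 2, 3, 4, 4.5, 5, 6, 7, 8)
    pitch <- if (is.null(geo$pitch)) 1 else geo$pitch
    cfg <- do.call(rsaSimulationConfig, as.list(simArgs))
    arch <- buildTaprootArchitecture(seed = seed)
    runs <- lapply(depths, function(d) {
      s <- rasterizeRsaSample(rsaSampleSpec(d, pitch = pitch), arch)
      simulateSample(s, cfg)
    })
    for (i in seq_along(depths))
      writeSurfaceSequence(runs[[i]],
        put(file.path(outdir, sprintf("rsa_depth_%s.tiff", depths[i]))),
        put(file.path(outdir, sprintf("rsa_depth_%s.csv", depths[i]))),
        put(file.path(outdir, sprintf("rsa_depth_%s.json", depths[i]))))
    cc <- depthTemperatureCorrelation(runs, depths,
                                      times = seq(10, cfg@totalDuration, by = 10))
    utils::write.csv(cc, put(file.path(outdir, "depth_cc.csv")), row.names = FALSE)
    for (i in seq_along(depths)) {
      det <- detectRoots(runs[[i]])
      s <- rasterizeRsaSample(rsaSampleSpec(depths[i], pitch = pitch), arch)
      ev <- overlayEvaluation(det, truthMask(s))
      writeMaskPng(ev$composite,
                   put(file.path(outdir, sprintf("detect_%s.png", depths[i]))))
    }
  } else if (config$scenario == "rsa-sweep") {
    pitch <- if (is.null(geo$pitch)) 1 else geo$pitch
    cfg <- do.call(rsaSimulationConfig, as.list(simArgs))
    arch <- buildTaprootArchitecture(seed = seed)
    runs <- parameterSweep(rsaSampleSpec(2, pitch = pitch), arch, cfg,
                           axis = "flux", values = c(0.0005, 0.0010, 0.0015))
    for (nm in names(runs))
      writeSurfaceSequence(runs[[nm]],
        put(file.path(outdir, paste0(gsub("[^0-9a-z.]", "_", nm), ".tiff"))),
        put(file.path(outdir, paste0(gsub("[^0-9a-z.]", "_", nm), ".csv"))),
        put(file.path(outdir, paste0(gsub("[^0-9a-z.]", "_", nm), ".json"))))
  } else if (config$scenario %in% c("bubble-grid", "bubble-validate")) {
    pitch <- if (is.null(geo$bubblePitch)) 1 else geo$bubblePitch
    cfg <- do.call(bubbleSimulationConfig, as.list(simArgs))
    grid <- if (config$scenario == "bubble-grid") bubbleTrainingGrid()
            else bubbleValidationGrid()
    fm <- simulateBubbleGrid(grid, pitch = pitch, config = cfg)
    writeFeatureMatrix(fm, put(file.path(outdir, "bubble_features.csv")))
  } else if (config$scenario == "noise-battery") {
    stop("the noise-battery scenario needs precomputed features; ",
         "call runNoiseBattery() directly")
  }

  yaml::write_yaml(config, put(file.path(outdir, "config.yaml")))
  manifest <- list(
    scenario = config$scenario, seed = seed,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
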
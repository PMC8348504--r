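# Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

rsaDepths <- function() c(1, 2, 3, 4, 4.5, 5, 6, 7, 8)

# the nine-depth study battery at the default 1 mm pitch (about 30 s)
rsaBattery <- function() memoFixture("rsaBattery", {
  arch <- buildTaprootArchitecture(seed = 1L)
  runs <- suppressWarnings(lapply(rsaDepths(), function(d)
    simulateSample(rasterizeRsaSample(rsaSampleSpec(d), arch),
                   rsaSimulationConfig())))
  list(arch = arch, depths = rsaDepths(), runs = runs)
})

# per-point feature matrices over the battery
rsaFeatureSets <- function() memoFixture("rsaFeatureSets", {
  b <- rsaBattery()
  list(
    fm1 = extractPointFeatures(b$runs, selectFeaturePoints(b$arch, 1), b$depths),
    fm3 = extractPointFeatures(b$runs, selectFeaturePoints(b$arch, 3), b$depths),
    X   = runMeanFeatures(b$runs))
})

# the full 77 + 12 bubble grids at 0.5 mm pitch (about 4 min)
bubbleGridRuns <- function() memoFixture("bubbleGridRuns", {
  list(tr = simulateBubbleGrid(bubbleTrainingGrid()),
       va = simulateBubbleGrid(bubbleValidationGrid()))
})

# small homogeneous soil block with one vertical root, for solver tests
smallRootSample <- function(pitch = 1) {
  suppressWarnings(rasterizeRsaSample(
    rsaSampleSpec(2, pitch = pitch, width = 10, height = 10, totalDepth = 12),
    rootArchitecture(data.frame(x0 = 5, y0 = 2, x1 = 5, y1 = 8,
                                diameter = 1, type = "primary",
                                stringsAsFactors = FALSE),
                     width = 10, height = 10)))
}

# 1-D graded acrylic column approximating a semi-infinite solid
acrylicColumn <- function() {
  m <- ThermoTrace:::materialTable(list(defaultMaterials()$acrylic))
  dz <- c(rep(0.02, 25), rep(0.1, 15), rep(0.5, 26))    # 15 mm deep
  new("VoxelSample", materialId = array(1L, c(1L, 1L, length(dz))),
      materials = m, pitch = 10, dz = dz,
      mask = matrix(FALSE, 1, 1), meta = list())
}

# surface sequence with externally supplied frames (for unit tests)
syntheticSequence <- function(frames, times, heatDuration = 0,
                              pitch = 1) {
  cfg <- simulationConfig(flux = 0, heatDuration = heatDuration,
                          totalDuration = max(times), ambient = 296.15,
                          frameInterval = 1)
  new("SurfaceSequence", frames = frames, times = times,
      meta = list(config = cfg, pitch = pitch))
}

# brute-force strict-valley finder (independent oracle for localMinima)
strictValleys <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(vapply(2:(n - 1L), function(i)
    x[i] < x[i - 1L] && x[i] < x[i + 1L], logical(1))) + 1L
}
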
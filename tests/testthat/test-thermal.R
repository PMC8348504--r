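test_that("equilibrium is a fixed point of both stepping schemes", {
  s <- smallRootSample()
  for (m in c("explicit", "implicit")) {
    cfg <- simulationConfig(flux = 0, heatDuration = 0, totalDuration = 10,
                            ambient = 296.15, method = m, dt = 0.5)
    run <- simulateSample(s, cfg)
    expect_true(all(run@frames == 296.15), info = m)
  }
})

test_that("insulated heating conserves energy to 0.1% at every frame", {
  s <- smallRootSample()
  E <- 0.0005 * 10 * 10 * 10                       # q * A * t_heat
  for (m in c("explicit", "implicit")) {
    cfg <- rsaSimulationConfig(h = 0, totalDuration = 40, method = m,
                               dt = if (m == "implicit") 0.5 else NA)
    run <- simulateSample(s, cfg)
    post <- frameTimes(run) >= 10
    expect_true(all(abs(enthalpyHistory(run)[post] / E - 1) < 1e-3), info = m)
  }
})

test_that("surface response matches the semi-infinite constant-flux solution", {
  run <- simulateSample(acrylicColumn(),
                        simulationConfig(flux = 5e-4, heatDuration = 5,
                                         totalDuration = 5, ambient = 296.15,
                                         h = 0, method = "implicit",
                                         dt = 0.005, frameInterval = 1))
  k <- 0.17
  alpha <- diffusivity(defaultMaterials()$acrylic)
  for (tt in 1:5) {
    Ts <- getFrame(run, which(abs(frameTimes(run) - tt) < 1e-9))[1, 1] - 296.15
    Tan <- 2 * 500 / k * sqrt(alpha * tt / pi)
    expect_lt(abs(Ts / Tan - 1), 0.03)
  }
})

test_that("total input energy is flux times area times duration", {
  expect_equal(totalInputEnergy(rsaSampleSpec(2), rsaSimulationConfig()), 30.875)
  expect_equal(totalInputEnergy(rsaSampleSpec(2), rsaSimulationConfig(flux = 0)), 0)
  expect_equal(totalInputEnergy(bubbleSampleSpec(2, 2), bubbleSimulationConfig()), 57.6)
  s <- smallRootSample()
  expect_equal(totalInputEnergy(s, rsaSimulationConfig()), 0.0005 * 100 * 10)
})

test_that("surface averaging and point traces are exact reductions", {
  fr <- array(296.15, c(4, 4, 3))
  sq <- syntheticSequence(fr, 0:2)
  expect_true(all(averageSurfaceTemperature(sq)$meanT == 296.15))

  chk <- matrix(rep(c(300, 302), 8), 4, 4)          # two-value checkerboard
  fr2 <- array(chk, c(4, 4, 2))
  sq2 <- syntheticSequence(fr2, 0:1)
  expect_equal(averageSurfaceTemperature(sq2)$meanT, c(301, 301))
  expect_error(averageSurfaceTemperature(sq2, c(5, 9)), "no frames")

  tr <- pointTrace(sq2, 2, 3, pixel = TRUE)
  expect_equal(tr$temperature, unname(fr2[2, 3, ]))
  expect_error(pointTrace(sq2, 9, 1, pixel = TRUE), "outside")
})

test_that("cooling-rate regression matches closed forms", {
  tt <- 0:20
  expect_equal(coolingRate(tt, 300 - 0.025 * tt), 0.025)
  # two-point oracle on linear data
  y <- 310 - 0.4 * tt
  expect_equal(coolingRate(tt, y), abs((y[21] - y[1]) / (tt[21] - tt[1])))
  expect_error(coolingRate(c(1, 1), c(2, 3)), "distinct time")
})

test_that("degree-6 cooling fits report a correct R-squared", {
  tt <- seq(0, 10, by = 0.5)
  y <- 3 + 0.5 * tt - 0.02 * tt^3 + 1e-4 * tt^6
  f <- fitCoolingPolynomial(tt, y)
  expect_equal(f$r.squared, 1, tolerance = 1e-9)

  set.seed(11)
  y2 <- rnorm(length(tt))
  f2 <- fitCoolingPolynomial(tt, y2)
  fit <- lm(y2 ~ poly(tt, 6, raw = TRUE))
  expect_equal(f2$r.squared,
               1 - sum(residuals(fit)^2) / sum((y2 - mean(y2))^2))
  expect_error(fitCoolingPolynomial(tt, rep(1, length(tt))), "zero variance")
})

test_that("depth-temperature correlation reproduces Pearson's formula", {
  mkRun <- function(val) syntheticSequence(array(val, c(2, 2, 3)), 0:2)
  runs <- lapply(c(300, 301, 302), mkRun)
  cc <- depthTemperatureCorrelation(runs, c(1, 2, 3), times = 1)
  expect_equal(cc$cc, 1)

  runs2 <- lapply(c(300, 304, 301), mkRun)
  cc2 <- depthTemperatureCorrelation(runs2, c(1, 2, 4), times = 2)
  x <- c(1, 2, 4); y <- c(300, 304, 301)
  expect_equal(cc2$cc,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_error(depthTemperatureCorrelation(lapply(c(1, 1, 1), mkRun),
                                           1:3, times = 0),
               "zero temperature variance")
})

test_that("maximum surface temperature is non-increasing while cooling", {
  run <- simulateSample(smallRootSample(), rsaSimulationConfig(totalDuration = 60))
  mx <- apply(run@frames, 3, max)
  cooling <- frameTimes(run) > 10
  expect_true(all(diff(mx[cooling]) <= 1e-9))
})

test_that("grid refinement leaves the late surface temperature stable", {
  arch <- rootArchitecture(
    data.frame(x0 = 10, y0 = 3, x1 = 10, y1 = 17, diameter = 1,
               type = "primary", stringsAsFactors = FALSE),
    width = 20, height = 20)
  late <- function(p) {
    s <- suppressWarnings(rasterizeRsaSample(
      rsaSampleSpec(2, pitch = p, width = 20, height = 20), arch))
    a <- averageSurfaceTemperature(simulateSample(s, rsaSimulationConfig()))
    a$meanT[a$time == 120]
  }
  expect_lt(abs(late(0.5) - late(1)), 0.05)
})

test_that("parameter sweeps preserve relative patterns and lose contrast", {
  arch <- rootArchitecture(
    data.frame(x0 = 10, y0 = 3, x1 = 10, y1 = 17, diameter = 1,
               type = "primary", stringsAsFactors = FALSE),
    width = 20, height = 20)
  spec <- rsaSampleSpec(2, pitch = 1, width = 20, height = 20)
  cfg <- rsaSimulationConfig(totalDuration = 40)

  one <- parameterSweep(spec, arch, cfg, axis = "flux", values = 0.0005)
  expect_length(one, 1L)
  ref <- simulateSample(rasterizeRsaSample(spec, arch), cfg)
  expect_equal(one[[1]]@frames, ref@frames)

  sw <- parameterSweep(spec, arch, cfg, axis = "flux",
                       values = c(0.0005, 0.0010, 0.0015))
  at30 <- lapply(sw, function(r)
    as.numeric(getFrame(r, which(frameTimes(r) == 30))) - 296.15)
  expect_gt(cor(at30[[1]], at30[[2]]), 0.99)
  expect_gt(cor(at30[[1]], at30[[3]]), 0.99)
  expect_gt(cor(at30[[2]], at30[[3]]), 0.99)

  covers <- parameterSweep(spec, arch, cfg, axis = "cover_thickness",
                           values = c(2, 4))
  contrast <- vapply(covers, function(r) {
    fr <- getFrame(r, which(frameTimes(r) == 30))
    max(abs(fr - apply(fr, 2, stats::median)[col(fr)]))
  }, numeric(1))
  expect_lt(contrast[[2]], contrast[[1]])
})

test_that("solver guards reject broken configurations", {
  s <- smallRootSample()
  expect_error(simulationConfig(flux = 1, heatDuration = 20, totalDuration = 10,
                                ambient = 296.15), "exceeds")
  expect_error(simulateSample(s, rsaSimulationConfig(frameInterval = 7)),
               "multiples of the frame interval")
  expect_message(
    simulateSample(s, rsaSimulationConfig(totalDuration = 5, heatDuration = 5,
                                          method = "explicit", dt = 5)),
    "shrinking")
})
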
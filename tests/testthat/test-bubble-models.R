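test_that("the training and validation grids match the printed designs", {
  tr <- bubbleTrainingGrid()
  va <- bubbleValidationGrid()
  expect_identical(nrow(tr), 77L)
  expect_identical(nrow(va), 12L)
  expect_length(intersect(paste(tr$diameter, tr$depth),
                          paste(va$diameter, va$depth)), 0L)
  expect_setequal(unique(va$diameter), c(2.18, 3.38, 4.57, 6.35))
  expect_setequal(unique(va$depth), c(3.18, 4.76, 6.35))
})

test_that("bubble features are 40 baseline-subtracted cooling samples", {
  s <- buildBubbleSample(bubbleSampleSpec(4.37, 3.18, pitch = 1))
  cfg <- bubbleSimulationConfig(dt = 3, frameInterval = 3)

  run0 <- simulateSample(s, bubbleSimulationConfig(flux = 0, dt = 3,
                                                   frameInterval = 3))
  f0 <- extractBubbleFeatures(run0)
  expect_length(f0, 40L)
  expect_lt(max(abs(f0)), 1e-9)                      # zero-flux run

  run <- simulateSample(s, cfg)
  f <- extractBubbleFeatures(run)
  expect_length(f, 40L)
  expect_equal(as.numeric(names(f)), seq(30, 147, by = 3))

  # uniform shift of initial/ambient temperature leaves features unchanged
  # exactly for the linear (convection-only) physics ...
  cfgLin <- bubbleSimulationConfig(emissivity = 0, dt = 3, frameInterval = 3)
  fLin <- extractBubbleFeatures(simulateSample(s, cfgLin))
  cfgLinShift <- bubbleSimulationConfig(emissivity = 0, ambient = 303.15,
                                        dt = 3, frameInterval = 3)
  fLinShift <- extractBubbleFeatures(simulateSample(s, cfgLinShift))
  expect_equal(fLinShift, fLin, tolerance = 1e-8)
  # ... and to well under 1% once the T^4 radiation term is on
  cfgShift <- bubbleSimulationConfig(ambient = 303.15, dt = 3,
                                     frameInterval = 3)
  fShift <- extractBubbleFeatures(simulateSample(s, cfgShift))
  expect_lt(max(abs(fShift - f) / abs(f)), 0.01)

  shortCfg <- bubbleSimulationConfig(totalDuration = 90, dt = 3,
                                     frameInterval = 3)
  expect_error(extractBubbleFeatures(simulateSample(s, shortCfg)),
               "required")
})

test_that("bubble networks learn constructed noiseless targets", {
  # two latent factors drive every feature column, as cooling curves are
  # driven by the cone's diameter and depth
  set.seed(5)
  u <- runif(100); v <- runif(100)
  A <- runif(40, -1, 1); B <- runif(40, -1, 1)
  X <- outer(u, A) + outer(v, B)
  lab <- data.frame(diameter = 2 + 4 * u, depth = 2 + 5 * v)
  mk <- function(rows) new("FeatureMatrix",
                           features = X[rows, , drop = FALSE],
                           labels = lab[rows, , drop = FALSE],
                           times = seq(30, 147, 3), meta = list())
  tr <- mk(1:75); va <- mk(76:100)

  cfg <- annConfig(hiddenRange = c(3L, 5L), seed = 2, maxit = 1000,
                   decay = 1e-5)
  mimo <- fitMimo(tr, va, cfg)
  expect_true(all(mimo$validationAccuracy >= 99))
  expect_identical(dim(mimo$perCellAccuracy), c(25L, 2L))

  miso <- fitMiso(tr, va, "depth", cfg)
  expect_gte(miso$validationAccuracy, 99)

  expect_error(fitMimo(mk(1), va), "one training sample")
  labConst <- lab; labConst$depth <- 3
  trBad <- new("FeatureMatrix", features = X[1:75, ],
               labels = labConst[1:75, ], times = seq(30, 147, 3),
               meta = list())
  expect_error(fitMiso(trBad, va, "depth"), "constant")
})

test_that("larger cone volumes give higher late-cooling features", {
  g <- bubbleGridRuns()
  lab <- featureLabels(g$tr)
  late <- rowMeans(featureValues(g$tr)[, 30:40])
  vol <- pi * (lab$diameter / 2)^2 * (7.152 - lab$depth) / 3
  expect_gt(cor(vol, late, method = "spearman"), 0.9)
  for (d in unique(lab$depth)) {
    i <- which(lab$depth == d)
    expect_gt(late[i][which.max(lab$diameter[i])],
              late[i][which.min(lab$diameter[i])])
  }
})
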
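test_that("feature point sets have the documented sizes and structure", {
  arch <- buildTaprootArchitecture()
  s1 <- selectFeaturePoints(arch, 1)
  s2 <- selectFeaturePoints(arch, 2)
  s3 <- selectFeaturePoints(arch, 3)
  expect_identical(nrow(s1), 30L)
  expect_identical(nrow(s2), 30L)
  expect_identical(nrow(s3), 54L)

  # set 3 equals the brute-force union of sets 1 and 2
  u <- rbind(s1, s2)
  u <- u[!duplicated(round(u, 9)), ]
  expect_identical(nrow(u), 54L)
  expect_setequal(paste(round(s3$x, 6), round(s3$y, 6)),
                  paste(round(u$x, 6), round(u$y, 6)))

  # all set-1 points sit on the central branch
  expect_true(all(abs(s1$x - arch@segments$x0[1]) < 1e-9))
})

test_that("point-feature extraction yields 34 features and the row counts", {
  b <- rsaBattery()
  f <- rsaFeatureSets()
  expect_identical(dim(featureValues(f$fm1)), c(270L, 34L))
  expect_identical(dim(featureValues(f$fm3)), c(486L, 34L))
  expect_identical(featureLabels(f$fm1)$depth, rep(b$depths, each = 30))

  one <- extractPointFeatures(b$runs[1], data.frame(x = 32.5, y = 40),
                              b$depths[1])
  expect_identical(dim(featureValues(one)), c(1L, 34L))
  expect_equal(featureTimes(one), seq(11, by = 3, length.out = 34))

  short <- simulateSample(smallRootSample(), rsaSimulationConfig(totalDuration = 40))
  expect_error(extractPointFeatures(list(short), data.frame(x = 5, y = 5), 2),
               "cooling window too short")
})

test_that("relative-error accuracy matches hand-computed values", {
  expect_equal(eq7Accuracy(4, 4), 100)
  expect_equal(eq7Accuracy(4.5, 4), 87.5)
  expect_equal(eq7Accuracy(12.175, 4), 100 * (1 - 8.175 / 4))  # about -104.4
  expect_lt(eq7Accuracy(12.175, 4), 0)
  expect_error(eq7Accuracy(1, 0), "non-zero")

  # joint positive rescaling of outputs and targets leaves accuracy unchanged
  set.seed(42)
  for (i in 1:20) {
    o <- runif(5, 1, 10); tg <- runif(5, 1, 10); lam <- runif(1, 0.1, 50)
    expect_equal(eq7Accuracy(lam * o, lam * tg), eq7Accuracy(o, tg))
  }
})

test_that("polynomial depth regression is exact in the linear full-rank case", {
  set.seed(7)
  X <- matrix(rnorm(9 * 7), 9, 7)
  beta <- rnorm(7)
  depths <- as.numeric(X %*% beta + 2)
  f <- fitPolynomialRegression(X, depths, target = 5)
  expect_equal(f$prediction, depths[5], tolerance = 1e-6)
  expect_equal(f$absError, 0, tolerance = 1e-6)

  # with 8 equations and 8 unknowns of full rank the training rows are
  # reproduced exactly (linear-algebra oracle)
  tr <- setdiff(1:9, 5)
  fitted <- as.numeric(cbind(X[tr, ], 1) %*% c(f$coefficients, f$intercept))
  expect_equal(fitted, depths[tr], tolerance = 1e-6)
})

test_that("interior depths are easier to predict than extrapolated ones", {
  b <- rsaBattery()
  X <- rsaFeatureSets()$X
  pi_ <- prBattery(X, b$depths, "interpolation")
  pe <- prBattery(X, b$depths, "extrapolation")
  expect_identical(nrow(pi_$results), 7L)
  expect_identical(nrow(pe$results), 2L)
  expect_lt(pi_$meanAbsError, pe$meanAbsError)
})

test_that("the SVM classifier separates constructed blobs and guards inputs", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20 * 3, 0), 20, 3), matrix(rnorm(20 * 3, 8), 20, 3))
  fm <- new("FeatureMatrix", features = X,
            labels = data.frame(depth = rep(c(1, 2), each = 20)),
            times = 1:3, meta = list())
  m <- fitSvm(fm, svmConfig(costGrid = 2^(0:2), gammaGrid = 2^(-2:0), seed = 3))
  expect_equal(m$validationAccuracy, 100)
  expect_gte(m$trainAccuracy, m$validationAccuracy - 0.5)

  fmBad <- new("FeatureMatrix", features = X,
               labels = data.frame(depth = rep(1, 40)), times = 1:3,
               meta = list())
  expect_error(fitSvm(fmBad), "two depth classes")

  one <- fitSvm(fm, svmConfig(costGrid = 4, gammaGrid = 0.5, seed = 3))
  expect_equal(one$cost, 4)
  expect_equal(one$gamma, 0.5)
})

test_that("K-fold selection learns a noiseless linear response", {
  set.seed(9)
  X <- cbind(runif(60, 0, 1), matrix(runif(60 * 4), 60, 4))
  y <- 2 + 3 * X[, 1]
  fm <- new("FeatureMatrix", features = X, labels = data.frame(depth = y),
            times = 1:5, meta = list())
  m <- fitAnnKfold(fm, annConfig(hiddenRange = c(2L, 3L), seed = 4,
                                 maxit = 500))
  expect_gte(m$validationAccuracy, 99)
  expect_lt(m$validationAbsError, 0.1)
  expect_true(m$hidden %in% c(2L, 3L))

  # leave-one-out (K = training rows) degenerates gracefully
  small <- new("FeatureMatrix", features = X[1:12, ],
               labels = data.frame(depth = y[1:12]), times = 1:5,
               meta = list())
  mLoo <- fitAnnKfold(small, annConfig(hiddenRange = 2L, folds = 8L,
                                       seed = 4, maxit = 200))
  expect_true(is.finite(mLoo$validationAccuracy))

  fmConst <- new("FeatureMatrix", features = X,
                 labels = data.frame(depth = rep(2, 60)), times = 1:5,
                 meta = list())
  expect_error(fitAnnKfold(fmConst), "zero variance")
})

test_that("depth networks recover burial depth on the study battery", {
  f <- rsaFeatureSets()
  ann <- fitAnnKfold(f$fm1, annConfig(hiddenRange = c(2L, 5L, 9L, 14L, 20L,
                                                      27L, 33L), seed = 1))
  expect_lt(ann$validationAbsError, 1.5)
  expect_gte(ann$trainAccuracy, ann$validationAccuracy - 2)

  sv <- fitSvm(f$fm1, svmConfig(seed = 1))
  expect_gte(sv$trainAccuracy, sv$validationAccuracy - 0.5)
  expect_gte(sv$validationAccuracy, 60)
})
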
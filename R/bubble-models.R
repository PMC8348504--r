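#' Bubble training and validation grids
#'
#' The simulated bubble geometries: 11 cone base diameters crossed with 7
#' apex depths give the 77 training cells; 4 further diameters crossed
#' with 3 depths give the 12 validation cells.  The validation diameter
#' 6.35 mm lies outside the training range — a deliberate extrapolation
#' kept as printed.
#'
#' @return data.frame with columns `diameter`, `depth` (mm).
#' @examples
#' nrow(bubbleTrainingGrid())    # 77
#' nrow(bubbleValidationGrid())  # 12
#' @export
bubbleTrainingGrid <- function() {
  g <- expand.grid(
    diameter = c(1.98, 2.38, 4.37, 5.95, 2.78, 3.18, 3.58, 3.98, 4.87, 5.27, 5.67),
    depth    = c(1.59, 3.18, 4.76, 2.38, 3.97, 5.56, 6.35))
  g[order(g$diameter, g$depth), , drop = FALSE]
}

#' @rdname bubbleTrainingGrid
#' @export
bubbleValidationGrid <- function() {
  g <- expand.grid(diameter = c(2.18, 3.38, 4.57, 6.35),
                   depth    = c(3.18, 4.76, 6.35))
  g[order(g$diameter, g$depth), , drop = FALSE]
}

#' Baseline-subtracted cooling features of a bubble run
#'
#' Mean upper-surface temperature at t = 30, 33, ..., 147 s (40 values,
#' sampled every 3 s from the end of heating) minus the initial
#' temperature, which makes the features invariant to a uniform shift of
#' the ambient/initial temperature.
#'
#' @param seq a [SurfaceSequence-class] covering 30-150 s.
#' @param initial baseline temperature (K); default = the run's
#'   configured initial temperature.
#' @return Numeric vector of length 40 named by timestamp.
#' @export
extractBubbleFeatures <- function(seq, initial = NULL) {
  stopifnot(is(seq, "SurfaceSequence"))
  cfg <- seq@meta$config
  if (is.null(initial)) initial <- cfg@initial
  times <- seq(cfg@heatDuration, by = 3, length.out = 40L)
  a <- averageSurfaceTemperature(seq)
  i <- match(round(times, 6L), round(a$time, 6L))
  if (any(is.na(i)))
    stop("run lacks frames at the required 3-second sampling timestamps")
  stats::setNames(a$meanT[i] - initial, times)
}

#' Simulate a bubble grid into a feature matrix
#'
#' Builds, simulates and featurizes one bubble sample per grid row.
#'
#' @param grid data.frame with `diameter`, `depth` columns (mm).
#' @param pitch in-plane voxel pitch in mm.
#' @param config a [SimulationConfig-class]
#'   (default [bubbleSimulationConfig()]).
#' @param materials material library.
#' @param verbose print one line per run.
#' @return A [FeatureMatrix-class] with 40 columns and `diameter`,
#'   `depth` labels.
#' @export
simulateBubbleGrid <- function(grid, pitch = 0.5,
                               config = bubbleSimulationConfig(dt = 3,
                                                               frameInterval = 3),
                               materials = defaultMaterials(),
                               verbose = FALSE) {
  feats <- matrix(NA_real_, nrow(grid), 40L)
  for (i in seq_len(nrow(grid))) {
    sp <- bubbleSampleSpec(grid$diameter[i], grid$depth[i], pitch = pitch)
    run <- simulateSample(buildBubbleSample(sp, materials), config)
    feats[i, ] <- extractBubbleFeatures(run)
    if (verbose)
      message(sprintf("bubble D %.2f mm, depth %.2f mm done", grid$diameter[i],
                      grid$depth[i]))
  }
  new("FeatureMatrix", features = feats, labels = grid,
      times = seq(config@heatDuration, by = 3, length.out = 40L),
      meta = list(pitch = pitch, kind = "bubble"))
}

# shared trainer for the bubble networks: K-fold size selection on the
# training grid, refit, per-cell and average validation accuracy
bubbleAnnTrain <- function(trainX, trainY, validX, validY, config) {
  trainY <- as.matrix(trainY); validY <- as.matrix(validY)
  if (nrow(trainX) < 2L) stop("need more than one training sample")
  if (any(apply(trainY, 2L, var) == 0))
    stop("a target column is constant; R^2 selection is undefined")
  sc <- fitScaler(trainX)
  Xs <- applyScaler(trainX, sc)
  sel <- annKfoldSelect(Xs, trainY, config$hiddenRange, config$folds,
                        config$seed, config$maxit, config$decay)
  fit <- fitNnet(Xs, trainY, sel$hidden, config$seed + 7L,
                 config$maxit, config$decay)
  predTr <- predict(fit, Xs)
  predVa <- predict(fit, applyScaler(validX, sc))
  # per-validation-cell accuracy: the single-pair form of the accuracy
  # equation (no averaging), one value per cell and output
  perCell <- 100 * (1 - abs(predVa - validY) / abs(validY))
  colnames(perCell) <- colnames(trainY)
  structure(list(fit = fit, hidden = sel$hidden, cvTable = sel$table,
                 scaler = sc,
                 trainAccuracy = vapply(seq_len(ncol(trainY)), function(j)
                   eq7Accuracy(predTr[, j], trainY[, j]), numeric(1)),
                 validationAccuracy = vapply(seq_len(ncol(validY)), function(j)
                   eq7Accuracy(predVa[, j], validY[, j]), numeric(1)),
                 perCellAccuracy = perCell,
                 validationPredictions = predVa),
            class = "bubbleAnnModel")
}

#' Train the MIMO bubble network
#'
#' Single-hidden-layer network predicting cone diameter and depth jointly
#' from the 40 baseline-subtracted cooling features; hidden size chosen
#' in 3..39 by K-fold pooled R^2 on the 77-cell training grid, then
#' scored per cell and on average against the 12-cell validation grid.
#'
#' @param train,valid [FeatureMatrix-class] objects from
#'   [simulateBubbleGrid()] over the training and validation grids.
#' @param config an [annConfig()]; the default hidden range is 3:39.
#' @return list of class `bubbleAnnModel` with `hidden`,
#'   `trainAccuracy`, `validationAccuracy` (named diameter/depth),
#'   `perCellAccuracy` and predictions.
#' @export
fitMimo <- function(train, valid, config = annConfig(hiddenRange = 3:39)) {
  stopifnot(is(train, "FeatureMatrix"), is(valid, "FeatureMatrix"))
  m <- bubbleAnnTrain(train@features,
                      as.matrix(train@labels[, c("diameter", "depth")]),
                      valid@features,
                      as.matrix(valid@labels[, c("diameter", "depth")]),
                      config)
  names(m$trainAccuracy) <- names(m$validationAccuracy) <- c("diameter", "depth")
  m
}

#' Train a MISO bubble network
#'
#' As [fitMimo()] but with a single output, either the cone diameter or
#' the apex depth; the hidden-size search range is 2..39.
#'
#' @param train,valid [FeatureMatrix-class] objects.
#' @param target `"diameter"` or `"depth"`.
#' @param config an [annConfig()].
#' @return list of class `bubbleAnnModel`.
#' @export
fitMiso <- function(train, valid, target = c("diameter", "depth"),
                    config = annConfig(hiddenRange = 2:39)) {
  target <- match.arg(target)
  stopifnot(is(train, "FeatureMatrix"), is(valid, "FeatureMatrix"))
  m <- bubbleAnnTrain(train@features,
                      matrix(train@labels[[target]], ncol = 1,
                             dimnames = list(NULL, target)),
                      valid@features,
                      matrix(valid@labels[[target]], ncol = 1,
                             dimnames = list(NULL, target)),
                      config)
  names(m$trainAccuracy) <- names(m$validationAccuracy) <- target
  m
}
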
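#' Noise-injection specification
#'
#' Zero-mean Gaussian noise of a stated standard deviation added to a
#' stated fraction of training samples (whole rows, every feature), the
#' fault-tolerance probe applied to every predictor.  Injecting into
#' 100% of the rows is rejected: it would sever the relationship between
#' training input and output.
#'
#' @param ratio percent of training rows to perturb, in `[0, 100)`.
#' @param sd standard deviation of the added noise (K); the root study
#'   uses 0.02/0.04/0.06, the bubble study 0.1/0.2/0.3.
#' @param seed RNG seed.
#' @return list of class `noiseSpec`.
#' @export
noiseSpec <- function(ratio, sd, seed = 1L) {
  stopifnot(ratio >= 0, sd >= 0)
  if (ratio >= 100)
    stop("injecting noise into 100% of the training input is rejected")
  structure(list(ratio = ratio, sd = sd, seed = as.integer(seed)),
            class = "noiseSpec")
}

#' Inject Gaussian noise into a feature matrix
#'
#' A seeded uniformly random subset of rows of the stated ratio receives
#' additive zero-mean Gaussian noise of the stated SD on every feature;
#' the remaining rows are untouched.  Ratio 0 or SD 0 return the input
#' bit-exactly.
#'
#' @param x a [FeatureMatrix-class] or plain numeric matrix.
#' @param spec a [noiseSpec()].
#' @return Same type as `x`.
#' @export
injectNoise <- function(x, spec) {
  stopifnot(inherits(spec, "noiseSpec"))
  isFm <- is(x, "FeatureMatrix")
  X <- if (isFm) x@features else x
  if (spec$ratio > 0 && spec$sd > 0) {
    n <- nrow(X)
    k <- round(spec$ratio / 100 * n)
    withr::with_seed(spec$seed, {
      rows <- sample(n, k)
      X[rows, ] <- X[rows, , drop = FALSE] +
        matrix(rnorm(k * ncol(X), 0, spec$sd), k, ncol(X))
    })
  }
  if (isFm) { x@features <- X; x } else X
}

#' Run a noise battery over a predictor
#'
#' For the baseline cell plus every (ratio, SD) combination, noise is
#' injected into the training input only, the model is retrained with
#' its usual recipe, and the clean validation target is scored.  The
#' battery therefore has 1 + ratios x sds cells (10 by default).  Per-cell
#' failures are recorded as `NA` and the battery continues.
#'
#' @param kind `"pr"`, `"svm"`, `"ann"`, `"mimo"`, `"miso-diameter"` or
#'   `"miso-depth"`.
#' @param features for `"pr"`: the per-model mean-temperature matrix from
#'   [runMeanFeatures()]; otherwise a training [FeatureMatrix-class].
#' @param labels for `"pr"`: the depth vector; ignored otherwise (labels
#'   ride inside the feature matrix).
#' @param valid validation [FeatureMatrix-class] (bubble kinds only).
#' @param ratios injection ratios in percent.
#' @param sds noise standard deviations (K).
#' @param seed base RNG seed; each cell derives its own stream.
#' @param config model configuration ([svmConfig()] / [annConfig()])
#'   where applicable.
#' @return data.frame with columns `ratio`, `sd`, `accuracy` (percent;
#'   for `"mimo"` the mean of the diameter and depth accuracies) and
#'   `seconds` (informational training time).
#' @export
runNoiseBattery <- function(kind = c("pr", "svm", "ann", "mimo",
                                     "miso-diameter", "miso-depth"),
                            features, labels = NULL, valid = NULL,
                            ratios = c(10, 20, 30), sds = c(0.02, 0.04, 0.06),
                            seed = 1L, config = NULL) {
  kind <- match.arg(kind)
  cells <- rbind(data.frame(ratio = 0, sd = 0),
                 expand.grid(sd = sds, ratio = ratios)[, c("ratio", "sd")])
  trainOne <- function(noisy) {
    switch(kind,
      pr = prBattery(features, labels, "interpolation", trainX = noisy)$meanAccuracy,
      svm = {
        cfg <- if (is.null(config)) svmConfig() else config
        fm <- features; fm@features <- noisy
        fitSvm(fm, cfg)$validationAccuracy
      },
      ann = {
        cfg <- if (is.null(config)) annConfig() else config
        fm <- features; fm@features <- noisy
        fitAnnKfold(fm, cfg)$validationAccuracy
      },
      mimo = {
        cfg <- if (is.null(config)) annConfig(hiddenRange = 3:39) else config
        fm <- features; fm@features <- noisy
        mean(fitMimo(fm, valid, cfg)$validationAccuracy)
      },
      {
        tgt <- sub("miso-", "", kind)
        cfg <- if (is.null(config)) annConfig(hiddenRange = 2:39) else config
        fm <- features; fm@features <- noisy
        fitMiso(fm, valid, tgt, cfg)$validationAccuracy
      })
  }
  X0 <- if (is(features, "FeatureMatrix")) features@features else features
  # noise touches the training partition only; for split-based kinds the
  # trainer's own split is deterministic, so perturbing rows outside the
  # training index would leak into validation -- mask them back
  trainRows <- seq_len(nrow(X0))
  if (kind %in% c("svm", "ann")) {
    cfg <- if (is.null(config)) { if (kind == "svm") svmConfig() else annConfig() } else config
    trainRows <- withr::with_seed(cfg$seed,
      sort(sample(nrow(X0), round(cfg$split * nrow(X0)))))
  }
  out <- cells
  out$accuracy <- NA_real_
  out$seconds <- NA_real_
  for (i in seq_len(nrow(cells))) {
    noisy <- X0
    if (cells$ratio[i] > 0 && cells$sd[i] > 0) {
      sub <- injectNoise(X0[trainRows, , drop = FALSE],
                         noiseSpec(cells$ratio[i], cells$sd[i],
                                   seed + 97L * i))
      noisy[trainRows, ] <- sub
    }
    t0 <- proc.time()[["elapsed"]]
    acc <- tryCatch(trainOne(noisy), error = function(e) {
      warning(sprintf("battery cell ratio=%g sd=%g failed: %s",
                      cells$ratio[i], cells$sd[i], conditionMessage(e)))
      NA_real_
    })
    out$accuracy[i] <- acc
    out$seconds[i] <- proc.time()[["elapsed"]] - t0
  }
  out
}

#' Standard-deviation profile of per-model temperature data
#'
#' The spread of each simulated model's feature-source temperatures: one
#' SD per model, taken over all features and rows belonging to that
#' model.
#'
#' @param x a list of numeric matrices/vectors (one per model), or a
#'   [FeatureMatrix-class] whose rows are grouped by a label column.
#' @param by label column used for grouping when `x` is a
#'   [FeatureMatrix-class] (default `"depth"`).
#' @return Named numeric vector of standard deviations.
#' @export
temperatureSdProfile <- function(x, by = "depth") {
  if (is(x, "FeatureMatrix")) {
    g <- x@labels[[by]]
    vals <- split(as.data.frame(x@features), g)
    return(vapply(vals, function(v) sd(as.matrix(v)), numeric(1)))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  out <- vapply(x, function(v) sd(as.numeric(as.matrix(v))), numeric(1))
  if (is.null(names(out))) names(out) <- seq_along(out)
  out
}
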
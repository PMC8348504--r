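#' Prediction accuracy as percent of relative error
#'
#' `100 * (1 - mean(|output - target| / target))`: 100% at perfection,
#' unbounded below (large misses drive it negative).  Absolute relative
#' error is used so that signed errors cannot cancel.
#'
#' @param outputs,targets numeric vectors of equal length; targets must
#'   be non-zero.
#' @return Accuracy in percent.
#' @examples
#' eq7Accuracy(4.5, 4)      # 87.5
#' eq7Accuracy(12.175, 4)   # about -104.4
#' @export
eq7Accuracy <- function(outputs, targets) {
  stopifnot(length(outputs) == length(targets))
  if (any(targets == 0)) stop("targets must be non-zero for relative accuracy")
  100 * (1 - mean(abs(outputs - targets) / abs(targets)))
}

# Moore-Penrose pseudo-inverse via SVD (minimum-norm least squares)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Fit a leave-one-model-out polynomial depth regression
#'
#' Linear-in-features model `y = a1 x1 + ... + an xn + e` where the
#' features are the mean upper-surface temperatures at 60-120 s (7
#' features) and y is the burial depth.  All models except the target are
#' used for training (8 equations, 8 unknowns; solved by minimum-norm
#' least squares, so rank deficiency degrades gracefully), then the
#' target model's depth is predicted.
#'
#' @param X numeric matrix, one row per simulated model (features).
#' @param depths numeric vector of burial depths (mm).
#' @param target index of the held-out model.
#' @return list with `coefficients` (a1..an), `intercept`, `prediction`,
#'   `error` (signed, mm), `absError`, `accuracy` (percent) and `mode`
#'   (`"interpolation"` if the held-out depth is inside the training
#'   range, else `"extrapolation"`).
#' @export
fitPolynomialRegression <- function(X, depths, target) {
  stopifnot(nrow(X) == length(depths), target >= 1L, target <= nrow(X))
  Xtr <- X[-target, , drop = FALSE]
  ytr <- depths[-target]
  A <- cbind(Xtr, 1)
  beta <- as.numeric(pinv(A) %*% ytr)
  pred <- sum(X[target, ] * beta[-length(beta)]) + beta[length(beta)]
  mode <- if (depths[target] > min(ytr) && depths[target] < max(ytr))
    "interpolation" else "extrapolation"
  list(coefficients = beta[-length(beta)], intercept = beta[length(beta)],
       prediction = pred, error = pred - depths[target],
       absError = abs(pred - depths[target]),
       accuracy = eq7Accuracy(pred, depths[target]), mode = mode)
}

#' Leave-one-out battery of polynomial depth regressions
#'
#' Runs [fitPolynomialRegression()] over every interior depth
#' (interpolation) or over the shallowest and deepest depths
#' (extrapolation) and aggregates the unweighted mean absolute error and
#' mean accuracy.
#'
#' @param X numeric matrix of per-model features (see [runMeanFeatures()]).
#' @param depths burial depths (mm), one per row of `X`.
#' @param mode `"interpolation"` or `"extrapolation"`.
#' @param trainX optional feature matrix used for training rows instead
#'   of `X` (the noise battery trains on perturbed features while
#'   predicting the clean target).
#' @return list with `results` (per-target data.frame), `meanAbsError`
#'   and `meanAccuracy`.
#' @export
prBattery <- function(X, depths, mode = c("interpolation", "extrapolation"),
                      trainX = NULL) {
  mode <- match.arg(mode)
  if (is.null(trainX)) trainX <- X
  targets <- if (mode == "interpolation")
    which(depths > min(depths) & depths < max(depths))
  else c(which.min(depths), which.max(depths))
  res <- lapply(targets, function(tg) {
    Xmix <- trainX
    Xmix[tg, ] <- X[tg, ]                # the held-out row stays clean
    f <- fitPolynomialRegression(Xmix, depths, tg)
    data.frame(depth = depths[tg], prediction = f$prediction,
               error = f$error, absError = f$absError, accuracy = f$accuracy)
  })
  res <- do.call(rbind, res)
  list(results = res, meanAbsError = mean(res$absError),
       meanAccuracy = mean(res$accuracy))
}

#' SVM configuration
#'
#' @param costGrid,gammaGrid hyperparameter grids (log2-spaced by
#'   default, 2^-10 .. 2^10).
#' @param folds cross-validation folds for the grid search.
#' @param split training fraction of the data (remainder = validation).
#' @param seed RNG seed for the split.
#' @return list of class `svmConfig`.
#' @export
svmConfig <- function(costGrid = 2^seq(-10, 10, by = 2),
                      gammaGrid = 2^seq(-10, 10, by = 2),
                      folds = 5L, split = 2 / 3, seed = 1L) {
  stopifnot(length(costGrid) >= 1L, length(gammaGrid) >= 1L, folds >= 2L)
  structure(list(costGrid = sort(costGrid), gammaGrid = sort(gammaGrid),
                 folds = folds, split = split, seed = as.integer(seed)),
            class = "svmConfig")
}

#' Train the RBF SVM depth classifier
#'
#' One-vs-one RBF support vector classifier over the nine literal burial
#' depths as categorical labels.  The best (cost, gamma) pair is chosen
#' by cross-validated accuracy over the grid (ties broken toward smaller
#' cost, then smaller gamma); accuracy is the fraction of exactly
#' matching class labels.
#'
#' @param fm a [FeatureMatrix-class] (labels column `depth`).
#' @param config an [svmConfig()].
#' @return list of class `svmModel`: `model`, `cost`, `gamma`,
#'   `trainAccuracy`, `validationAccuracy` (percent), and the row indices
#'   of the split.
#' @export
fitSvm <- function(fm, config = svmConfig()) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- fm@features
  y <- factor(fm@labels$depth)
  if (nlevels(y) < 2L) stop("need at least two depth classes to train a classifier")
  n <- nrow(X)
  tr <- withr::with_seed(config$seed, sort(sample(n, round(config$split * n))))
  va <- setdiff(seq_len(n), tr)
  if (nlevels(droplevels(y[tr])) < 2L) stop("training split contains a single class")

  best <- NULL
  for (cst in config$costGrid) for (g in config$gammaGrid) {
    acc <- withr::with_seed(config$seed, {
      m <- e1071::svm(X[tr, ], y[tr], kernel = "radial", cost = cst,
                      gamma = g, cross = config$folds)
      m$tot.accuracy
    })
    if (is.null(best) || acc > best$acc + 1e-12)
      best <- list(cost = cst, gamma = g, acc = acc)
  }
  model <- e1071::svm(X[tr, ], y[tr], kernel = "radial",
                      cost = best$cost, gamma = best$gamma)
  accOf <- function(idx) 100 * mean(predict(model, X[idx, , drop = FALSE]) == y[idx])
  structure(list(model = model, cost = best$cost, gamma = best$gamma,
                 cvAccuracy = best$acc,
                 trainAccuracy = accOf(tr),
                 validationAccuracy = if (length(va)) accOf(va) else NA_real_,
                 trainIndex = tr, validationIndex = va),
            class = "svmModel")
}

#' ANN configuration
#'
#' @param hiddenRange candidate hidden-layer sizes (2..33 for the depth
#'   models; bubble models use 3..39 / 2..39).
#' @param folds K for the K-fold selection.
#' @param split training fraction (remainder = external validation).
#' @param seed RNG seed (split and weight initialization).
#' @param maxit,decay `nnet` optimizer settings.
#' @return list of class `annConfig`.
#' @export
annConfig <- function(hiddenRange = 2:33, folds = 5L, split = 2 / 3,
                      seed = 1L, maxit = 300L, decay = 1e-4) {
  stopifnot(length(hiddenRange) >= 1L, all(hiddenRange >= 1L), folds >= 2L)
  structure(list(hiddenRange = as.integer(hiddenRange), folds = as.integer(folds),
                 split = split, seed = as.integer(seed),
                 maxit = as.integer(maxit), decay = decay),
            class = "annConfig")
}

# standardize columns by training statistics
fitScaler <- function(X) {
  mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
  list(mu = mu, sg = sg)
}
applyScaler <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sg, "/")

# one seeded nnet fit (single hidden layer, linear output, MSE loss)
fitNnet <- function(X, Y, size, seed, maxit, decay) {
  withr::with_seed(seed, nnet::nnet(X, Y, size = size, linout = TRUE,
                                    maxit = maxit, decay = decay,
                                    trace = FALSE, MaxNWts = 100000L))
}

# K-fold hidden-size selection: pooled held-out R^2 per candidate size
# (pooling the fold predictions keeps R^2 defined down to leave-one-out)
annKfoldSelect <- function(X, Y, hiddenRange, folds, seed, maxit, decay) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  Y <- as.matrix(Y)
  r2 <- vapply(hiddenRange, function(h) {
    pred <- matrix(NA_real_, n, ncol(Y))
    for (f in seq_len(folds)) {
      te <- fold == f
      fit <- fitNnet(X[!te, , drop = FALSE], Y[!te, , drop = FALSE], h,
                     seed + 1000L * h + f, maxit, decay)
      pred[te, ] <- predict(fit, X[te, , drop = FALSE])
    }
    1 - sum((pred - Y)^2) / sum(sweep(Y, 2L, colMeans(Y))^2)
  }, numeric(1))
  list(hidden = hiddenRange[which.max(r2)],
       table = data.frame(hidden = hiddenRange, cvR2 = r2))
}

#' Train the K-fold-selected neural-network depth regressor
#'
#' Single-hidden-layer network predicting burial depth from the 34
#' cooling-phase temperature features.  The data are split 2/3 training /
#' 1/3 validation; for each candidate hidden size the training portion
#' is cross-validated K-fold and the pooled held-out R^2 recorded; the
#' best size is refit on the full training portion and scored on the
#' untouched validation third with [eq7Accuracy()].  Deterministic for a
#' fixed seed.
#'
#' @param fm a [FeatureMatrix-class] with a numeric `depth` label.
#' @param config an [annConfig()].
#' @return list of class `annModel`: `fit`, `hidden`, `cvTable`,
#'   `trainAccuracy`, `validationAccuracy`, `validationAbsError` (mm),
#'   `scaler`, split indices.
#' @export
fitAnnKfold <- function(fm, config = annConfig()) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- fm@features
  y <- fm@labels$depth
  if (var(y) == 0) stop("targets have zero variance; R^2 selection is undefined")
  n <- nrow(X)
  tr <- withr::with_seed(config$seed, sort(sample(n, round(config$split * n))))
  va <- setdiff(seq_len(n), tr)
  sc <- fitScaler(X[tr, , drop = FALSE])
  Xs <- applyScaler(X, sc)

  sel <- annKfoldSelect(Xs[tr, , drop = FALSE], y[tr], config$hiddenRange,
                        config$folds, config$seed, config$maxit, config$decay)
  fit <- fitNnet(Xs[tr, , drop = FALSE], y[tr], sel$hidden,
                 config$seed + 7L, config$maxit, config$decay)
  predTr <- as.numeric(predict(fit, Xs[tr, , drop = FALSE]))
  predVa <- as.numeric(predict(fit, Xs[va, , drop = FALSE]))
  structure(list(fit = fit, hidden = sel$hidden, cvTable = sel$table,
                 trainAccuracy = eq7Accuracy(predTr, y[tr]),
                 validationAccuracy = if (length(va)) eq7Accuracy(predVa, y[va]) else NA_real_,
                 validationAbsError = if (length(va)) mean(abs(predVa - y[va])) else NA_real_,
                 scaler = sc, trainIndex = tr, validationIndex = va),
            class = "annModel")
}

#' Predict with a trained annModel on new features
#'
#' @param model an `annModel` from [fitAnnKfold()].
#' @param X numeric feature matrix on the original scale.
#' @return numeric predictions.
#' @export
predictAnn <- function(model, X) {
  as.numeric(predict(model$fit, applyScaler(X, model$scaler)))
}
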
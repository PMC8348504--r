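#' Time-averaged surface temperature map
#'
#' Per-pixel arithmetic mean over a set of frames, by default all frames
#' of the cooling phase (t greater than the heating end).
#'
#' @param seq a [SurfaceSequence-class].
#' @param frames optional integer frame indices; default = cooling frames.
#' @return Numeric matrix `[nx, ny]` of mean temperatures (K).
#' @export
timeAverageMap <- function(seq, frames = NULL) {
  stopifnot(is(seq, "SurfaceSequence"))
  if (is.null(frames)) {
    cfg <- seq@meta$config
    if (is.null(cfg)) stop("sequence has no config metadata; pass frame indices")
    frames <- which(seq@times > cfg@heatDuration + 1e-9)
  }
  if (!length(frames)) stop("no frames selected for time averaging")
  apply(seq@frames[, , frames, drop = FALSE], c(1L, 2L), mean)
}

#' Local minima of a 1-D series
#'
#' Valley positions found by the literal difference/sign/difference rule:
#' take first differences, apply `sign()`, difference again, and flag
#' every position where the result is positive.  On plateaus
#' (`sign(0) = 0`) both plateau edges fire; this convention is kept
#' deliberately (see the package vignette) rather than restricting to
#' strict valleys.
#'
#' @param x numeric vector.
#' @return Integer vector of 1-based valley indices (empty when
#'   `length(x) < 3`).
#' @examples
#' localMinima(c(3, 1, 2, 0, 4))  # 2 and 4
#' @export
localMinima <- function(x) {
  if (length(x) < 3L) return(integer(0))
  unname(which(diff(sign(diff(as.numeric(x)))) > 0)) + 1L
}

# centred moving average with truncated (shrinking) edge windows,
# matching MATLAB movmean's default endpoint handling
movmeanTrunc <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (w - 1L - half))
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Line-scan detection of buried root structure
#'
#' Recovers root-region pixel coordinates from a surface sequence: the
#' cooling-phase frames are averaged per pixel; each constant-x line is
#' smoothed with a centred moving average and its local minima recorded
#' as candidate root pixels; the scan is repeated along constant-y lines;
#' the result is the union of both scans.  Buried roots cool the surface
#' above them (their heat capacity is far higher than the soil's), so the
#' time-averaged profile dips over a root.  No noise filtering is applied
#' by default — isolated spurious minima are part of the method's
#' reported behaviour — but an optional isolated-pixel filter can be
#' switched on.
#'
#' @param seq a [SurfaceSequence-class] covering the cooling phase.
#' @param window smoothing window in pixels (centred moving average,
#'   edges truncated; default 5).
#' @param frames optional frame indices to average (default: cooling).
#' @param dropIsolated if `TRUE`, remove detected pixels with no detected
#'   8-neighbour.
#' @return A [DetectionResult-class].
#' @export
detectRoots <- function(seq, window = 5L, frames = NULL, dropIsolated = FALSE) {
  avg <- timeAverageMap(seq, frames)
  nx <- nrow(avg); ny <- ncol(avg)
  if (window >= nx || window >= ny)
    stop("smoothing window must be shorter than both line lengths")
  map <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {                       # x-scan: lines of constant x
    idx <- localMinima(movmeanTrunc(avg[i, ], window))
    map[i, idx] <- TRUE
  }
  for (j in seq_len(ny)) {                       # y-scan: lines of constant y
    idx <- localMinima(movmeanTrunc(avg[, j], window))
    map[idx, j] <- TRUE
  }
  if (dropIsolated && any(map)) {
    nb <- neighbourCount(map)
    map <- map & nb > 0L
  }
  coords <- which(map, arr.ind = TRUE)
  colnames(coords) <- c("x", "y")
  new("DetectionResult", coords = coords, map = map,
      provenance = list(window = window,
                        frames = if (is.null(frames)) "cooling" else frames,
                        dropIsolated = dropIsolated))
}

# number of TRUE 8-neighbours for each cell of a logical matrix
neighbourCount <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0L, nx + 2L, ny + 2L)
  p[2:(nx + 1L), 2:(ny + 1L)] <- m
  out <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    out <- out + p[(2:(nx + 1L)) + dx, (2:(ny + 1L)) + dy]
  }
  out
}

# binary dilation by a square structuring element of the given radius
dilateMask <- function(m, radius) {
  if (radius <= 0L) return(m)
  nb <- m
  for (r in seq_len(radius)) nb <- nb | (neighbourCount(nb) > 0L)
  nb
}

#' Overlay evaluation of a detection against ground truth
#'
#' Builds the composite display image (truth scaled to 10% grey,
#' detection to 90%, then summed) and quantifies agreement: a detected
#' pixel is a true positive when it falls inside the truth mask dilated
#' by `tolerance` pixels; precision is the true-positive fraction of
#' detected pixels (1 when nothing is detected, by convention) and recall
#' the true-positive count over the truth pixel count, capped at 1.
#'
#' @param detected a [DetectionResult-class] or logical matrix.
#' @param truth logical matrix of the same dimensions.
#' @param tolerance dilation radius in pixels (default 1).
#' @return list with `composite` (numeric matrix with values in
#'   {0, 0.1, 0.9, 1}), `precision` and `recall`.
#' @export
overlayEvaluation <- function(detected, truth, tolerance = 1L) {
  if (is(detected, "DetectionResult")) detected <- detected@map
  stopifnot(is.logical(detected) || all(detected %in% c(0, 1)))
  detected <- detected != 0
  if (!identical(dim(detected), dim(truth)))
    stop("detected map and truth mask have different shapes")
  truth <- truth != 0
  composite <- 0.1 * truth + 0.9 * detected
  dil <- dilateMask(truth, tolerance)
  tp <- sum(detected & dil)
  precision <- if (sum(detected) == 0L) 1 else tp / sum(detected)
  recall <- if (sum(truth) == 0L) 1 else min(1, tp / sum(truth))
  list(composite = composite, precision = precision, recall = recall)
}

#' Deepest burial depth at which the central branch is recoverable
#'
#' Scans a battery of depth models from shallow to deep and reports the
#' deepest depth at which the line-scan method still recovers the main
#' central branch.  A branch row counts as resolved when (a) the
#' detection map marks a pixel inside the dilated central-branch band at
#' that row and (b) the dip of the smoothed time-averaged profile inside
#' the band exceeds the imaging noise floor — the camera's thermal
#' sensitivity (NETD) reduced by the frame averaging and the smoothing
#' window, `netd / sqrt(nFrames) / sqrt(window)`.  A depth succeeds when
#' at least half of the branch rows are resolved; the deepest success is
#' the largest depth reached without an intervening failure.
#'
#' @param runs list of [SurfaceSequence-class] objects, shallow to deep.
#' @param depths burial depths (mm), same order.
#' @param arch the [RootArchitecture-class] used for all runs; its first
#'   segment is the central primary branch.
#' @param netd camera thermal sensitivity in K (default 0.02, a typical
#'   NETD and the same quantum used by the noise battery).
#' @param window smoothing window of the line scan.
#' @param tolerance band dilation radius in pixels.
#' @param threshold resolved-row fraction required for success.
#' @return list with `depths`, `resolvedFraction`, `success` (logical)
#'   and `deepest` (mm; `NA` if even the shallowest model fails).
#' @export
deepestDetectableDepth <- function(runs, depths, arch, netd = 0.02,
                                   window = 5L, tolerance = 1L,
                                   threshold = 0.5) {
  stopifnot(length(runs) == length(depths))
  ord <- order(depths)
  runs <- runs[ord]; depths <- depths[ord]
  central <- rootArchitecture(arch@segments[1L, , drop = FALSE],
                              width = arch@width, height = arch@height)
  frac <- vapply(seq_along(runs), function(i) {
    spec <- runs[[i]]@meta$sampleMeta$spec
    cm <- truthMask(rasterizeRsaSample(spec, central))
    band <- dilateMask(cm, tolerance)
    bandCols <- which(rowSums(band) > 0)
    rowsTruth <- which(colSums(cm) > 0)
    det <- detectRoots(runs[[i]], window = window)
    avg <- timeAverageMap(runs[[i]])
    nCool <- length(which(runs[[i]]@times >
                            runs[[i]]@meta$config@heatDuration + 1e-9))
    floorSm <- netd / sqrt(nCool) / sqrt(window)
    resolved <- vapply(rowsTruth, function(j) {
      sm <- movmeanTrunc(avg[, j], window)
      any(det@map[bandCols, j]) &&
        (stats::median(sm) - min(sm[bandCols])) > floorSm
    }, logical(1))
    mean(resolved)
  }, numeric(1))
  success <- frac >= threshold
  deepest <- if (!success[1L]) NA_real_
             else depths[max(which(cumprod(success) == 1))]
  list(depths = depths, resolvedFraction = frac, success = success,
       deepest = deepest)
}

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d pixels flagged on a %d x %d frame (window %d)\n",
              nrow(object@coords), nrow(object@map), ncol(object@map),
              object@provenance$window))
})
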
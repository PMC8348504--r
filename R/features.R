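#' Select surface feature points on a root architecture
#'
#' Three deterministic point sets used as model inputs: set 1 is 30
#' points spaced uniformly along the central primary branch; set 2 is 30
#' points spread over the whole architecture, 6 of which are shared with
#' set 1; set 3 is their union (54 points).
#'
#' @param arch a [RootArchitecture-class] with at least one segment.
#' @param setId 1, 2 or 3.
#' @return data.frame with columns `x`, `y` (mm).
#' @examples
#' nrow(selectFeaturePoints(buildTaprootArchitecture(), 3))  # 54
#' @export
selectFeaturePoints <- function(arch, setId) {
  stopifnot(is(arch, "RootArchitecture"), setId %in% 1:3)
  seg <- arch@segments
  if (!nrow(seg)) stop("architecture has no segments to host feature points")
  pointsOn <- function(s, fr) {
    data.frame(x = s$x0 + fr * (s$x1 - s$x0), y = s$y0 + fr * (s$y1 - s$y0))
  }
  set1 <- pointsOn(seg[1L, ], seq(0.05, 0.95, length.out = 30L))
  if (setId == 1L) return(set1)

  shared <- set1[round(seq(3, 28, length.out = 6L)), ]
  others <- seg[-1L, , drop = FALSE]
  if (!nrow(others)) stop("architecture is too small to host the spread point set")
  lens <- sqrt((others$x1 - others$x0)^2 + (others$y1 - others$y0)^2)
  # 24 points distributed over the remaining branches, arc-length weighted
  nPer <- pmax(1L, round(24 * lens / sum(lens)))
  while (sum(nPer) > 24L) nPer[which.max(nPer)] <- nPer[which.max(nPer)] - 1L
  while (sum(nPer) < 24L) nPer[which.max(lens / nPer)] <- nPer[which.max(lens / nPer)] + 1L
  spread <- do.call(rbind, lapply(seq_len(nrow(others)), function(i) {
    pointsOn(others[i, ], seq(0.2, 0.8, length.out = nPer[i]))
  }))
  set2 <- rbind(shared, spread)
  rownames(set2) <- NULL
  if (setId == 2L) return(set2)

  u <- rbind(set1, set2)
  u <- u[!duplicated(round(u, 9L)), ]
  rownames(u) <- NULL
  u
}

#' Extract per-point cooling-phase temperature features
#'
#' For every feature point and every simulated model, samples the
#' point's surface temperature every `spacing` seconds starting at the
#' first recorded cooling frame, truncated to exactly `nSamples` values
#' (34 for the root study).  Row labels are the burial depths.
#'
#' @param runs list of [SurfaceSequence-class] objects sharing timing.
#' @param points data.frame with `x`, `y` columns (mm).
#' @param depths numeric vector of burial depths (mm), one per run.
#' @param nSamples number of temperature samples per point (default 34).
#' @param spacing sampling interval in seconds (default 3).
#' @return A [FeatureMatrix-class] with `length(points) * length(runs)`
#'   rows and a `depth` label column.
#' @export
extractPointFeatures <- function(runs, points, depths, nSamples = 34L,
                                 spacing = 3) {
  stopifnot(length(runs) == length(depths), nrow(points) >= 1L)
  t0 <- frameTimes(runs[[1L]])
  for (r in runs[-1L])
    if (!isTRUE(all.equal(frameTimes(r), t0))) stop("runs must share frame timing")
  cfg <- runs[[1L]]@meta$config
  cool <- t0[t0 > cfg@heatDuration + 1e-9]
  sampleTimes <- cool[1L] + spacing * (seq_len(nSamples) - 1L)
  if (max(sampleTimes) > max(t0) + 1e-9)
    stop(sprintf("cooling window too short: need samples up to t = %g s, have %g s",
                 max(sampleTimes), max(t0)))
  idx <- match(round(sampleTimes, 6L), round(t0, 6L))
  if (any(is.na(idx))) stop("required sampling timestamps are not recorded frames")

  rows <- vector("list", length(runs) * nrow(points))
  lab <- numeric(length(rows))
  r0 <- 0L
  for (m in seq_along(runs)) {
    fr <- runs[[m]]@frames
    pitch <- runs[[m]]@meta$pitch
    pi_ <- round(points$x / pitch + 0.5)
    pj <- round(points$y / pitch + 0.5)
    for (p in seq_len(nrow(points))) {
      r0 <- r0 + 1L
      rows[[r0]] <- fr[pi_[p], pj[p], idx]
      lab[r0] <- depths[m]
    }
  }
  new("FeatureMatrix", features = do.call(rbind, rows),
      labels = data.frame(depth = lab), times = sampleTimes,
      meta = list(points = points, spacing = spacing))
}

#' Accessors for FeatureMatrix
#'
#' @param x a [FeatureMatrix-class].
#' @return `featureValues`: the numeric matrix; `featureLabels`: the
#'   label data.frame; `featureTimes`: the sampling timestamps.
#' @name feature-accessors
NULL

#' @rdname feature-accessors
#' @export
featureValues <- function(x) x@features
#' @rdname feature-accessors
#' @export
featureLabels <- function(x) x@labels
#' @rdname feature-accessors
#' @export
featureTimes <- function(x) x@times

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (t = %g..%g s), labels: %s\n",
              nrow(object@features), ncol(object@features),
              min(object@times), max(object@times),
              paste(names(object@labels), collapse = ", ")))
})

#' Mean-surface-temperature features of the nine depth models
#'
#' The polynomial-regression inputs: one row per simulated model, columns
#' = the mean upper-surface temperature at the requested timestamps
#' (default 60, 70, ..., 120 s).
#'
#' @param runs list of [SurfaceSequence-class] objects.
#' @param times feature timestamps in seconds.
#' @return Numeric matrix `[length(runs), length(times)]`.
#' @export
runMeanFeatures <- function(runs, times = seq(60, 120, by = 10)) {
  t(vapply(runs, function(r) {
    a <- averageSurfaceTemperature(r)
    i <- match(round(times, 6L), round(a$time, 6L))
    if (any(is.na(i))) stop("requested feature timestamps are not recorded frames")
    a$meanT[i]
  }, numeric(length(times))))
}
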
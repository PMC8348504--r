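#' Average surface temperature over time
#'
#' Per-frame arithmetic mean over all surface pixels, optionally
#' restricted to a time window.
#'
#' @param seq a [SurfaceSequence-class].
#' @param window optional `c(t0, t1)` in seconds (inclusive).
#' @return data.frame with columns `time` (s) and `meanT` (K).
#' @export
averageSurfaceTemperature <- function(seq, window = NULL) {
  stopifnot(is(seq, "SurfaceSequence"))
  keep <- rep(TRUE, length(seq@times))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- seq@times >= window[1L] - 1e-9 & seq@times <= window[2L] + 1e-9
    if (!any(keep)) stop("time window contains no frames")
  }
  data.frame(time = seq@times[keep],
             meanT = apply(seq@frames[, , keep, drop = FALSE], 3L, mean))
}

#' Temperature trajectory of a single surface point
#'
#' Nearest-pixel temperature trace at physical coordinates (mm) or at a
#' pixel index.
#'
#' @param seq a [SurfaceSequence-class].
#' @param x,y point coordinates: mm when `pixel = FALSE` (default),
#'   1-based pixel indices when `pixel = TRUE`.
#' @param pixel interpret `x`, `y` as pixel indices.
#' @return data.frame with columns `time` (s) and `temperature` (K).
#' @export
pointTrace <- function(seq, x, y, pixel = FALSE) {
  stopifnot(is(seq, "SurfaceSequence"))
  d <- dim(seq@frames)
  if (!pixel) {
    pitch <- seq@meta$pitch
    if (is.null(pitch)) stop("sequence metadata lacks the pixel pitch; use pixel = TRUE")
    i <- round(x / pitch + 0.5); j <- round(y / pitch + 0.5)
  } else { i <- as.integer(x); j <- as.integer(y) }
  if (i < 1L || i > d[1L] || j < 1L || j > d[2L])
    stop(sprintf("point (%g, %g) lies outside the %d x %d frame", x, y, d[1L], d[2L]))
  data.frame(time = seq@times, temperature = seq@frames[i, j, ])
}

#' Cooling rate of a temperature series
#'
#' Magnitude of the least-squares slope of temperature against time over
#' the chosen window, K s^-1.
#'
#' @param times,values numeric vectors (s, K).
#' @param window optional `c(t0, t1)` restriction.
#' @return Cooling rate in K s^-1 (non-negative).
#' @export
coolingRate <- function(times, values, window = NULL) {
  stopifnot(length(times) == length(values))
  if (!is.null(window)) {
    keep <- times >= window[1L] - 1e-9 & times <= window[2L] + 1e-9
    times <- times[keep]; values <- values[keep]
  }
  if (length(times) < 2L || var(times) == 0)
    stop("cooling rate needs at least two distinct time points in the window")
  abs(sum((times - mean(times)) * (values - mean(values))) /
        sum((times - mean(times))^2))
}

#' Polynomial fit of a cooling curve
#'
#' Least-squares polynomial fit (default degree 6) of temperature against
#' time with the coefficient of determination R^2 = 1 - SSres/SStot.
#'
#' @param times,values numeric vectors.
#' @param degree polynomial degree.
#' @return list with `coefficients` (intercept first) and `r.squared`.
#' @export
fitCoolingPolynomial <- function(times, values, degree = 6L) {
  stopifnot(length(times) == length(values))
  if (length(times) < degree + 2L)
    stop(sprintf("need at least %d samples for a degree-%d fit", degree + 2L, degree))
  if (var(values) == 0) stop("series has zero variance; R^2 is undefined")
  fit <- lm(values ~ stats::poly(times, degree, raw = TRUE))
  ss <- sum(stats::residuals(fit)^2)
  list(coefficients = unname(coef(fit)),
       r.squared = 1 - ss / sum((values - mean(values))^2))
}

#' Correlation between burial depth and mean surface temperature
#'
#' Pearson correlation, at each requested timestamp, between the burial
#' depths of a set of simulated models and their mean upper-surface
#' temperatures at that time.
#'
#' @param runs list of [SurfaceSequence-class] objects sharing timing.
#' @param depths numeric vector of burial depths (mm), one per run.
#' @param times timestamps (s) at which to evaluate; default all shared
#'   frame times.
#' @return data.frame with columns `time` and `cc`.
#' @export
depthTemperatureCorrelation <- function(runs, depths, times = NULL) {
  stopifnot(length(runs) == length(depths), length(runs) >= 3L)
  t0 <- frameTimes(runs[[1L]])
  for (r in runs[-1L])
    if (!isTRUE(all.equal(frameTimes(r), t0))) stop("runs must share frame timing")
  if (is.null(times)) times <- t0
  M <- vapply(runs, function(r) apply(r@frames, 3L, mean), numeric(length(t0)))
  cc <- vapply(times, function(tt) {
    i <- which.min(abs(t0 - tt))
    if (abs(t0[i] - tt) > 1e-6) stop(sprintf("no frame at t = %g s", tt))
    v <- M[i, ]
    if (var(v) == 0)
      stop(sprintf("zero temperature variance across runs at t = %g s", tt))
    cor(depths, v)
  }, numeric(1))
  data.frame(time = times, cc = cc)
}

#' Sweep a boundary-condition or geometry parameter
#'
#' Re-simulates the root sample while varying one of: the heat flux, the
#' heating duration, or the acrylic cover thickness, holding the
#' architecture fixed.
#'
#' @param spec an [RsaSampleSpec-class] (the base geometry).
#' @param arch a [RootArchitecture-class], shared across runs.
#' @param config a [SimulationConfig-class] (the base conditions).
#' @param axis one of `"flux"`, `"heating_time"`, `"cover_thickness"`.
#' @param values numeric vector of parameter values.
#' @param materials material library for rasterization.
#' @return Named list of [SurfaceSequence-class], one per value.
#' @export
parameterSweep <- function(spec, arch, config,
                           axis = c("flux", "heating_time", "cover_thickness"),
                           values, materials = defaultMaterials()) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1L)
  out <- lapply(values, function(v) {
    sp <- spec; cf <- config
    if (axis == "flux") cf@flux <- v
    else if (axis == "heating_time") cf@heatDuration <- v
    else sp@coverThickness <- v
    simulateSample(rasterizeRsaSample(sp, arch, materials), cf)
  })
  names(out) <- paste0(axis, "=", values)
  out
}
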
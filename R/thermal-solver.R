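STEFAN_BOLTZMANN <- 5.670374419e-8   # W m^-2 K^-4

#' Create a simulation configuration
#'
#' @param flux heat flux applied to the top surface while heating, W mm^-2.
#' @param heatDuration,totalDuration seconds; heating must be a multiple
#'   of `frameInterval` so that frame times align with the heating end.
#' @param ambient ambient temperature, K.
#' @param initial initial temperature, K (defaults to `ambient`).
#' @param h natural-convection coefficient on the top surface, W m^-2 K^-1.
#'   The default 10 is a typical still-air value; it shifts absolute
#'   levels, not the orderings the pipeline relies on.
#' @param emissivity top-surface emissivity for radiative loss; 0 disables
#'   radiation (default for the root sample; 0.95 for the taped bubble
#'   sample).
#' @param dt time step in seconds, `NA` = automatic (explicit: from the
#'   stability bound; implicit: 0.5 s).
#' @param frameInterval seconds between recorded surface frames.
#' @param method `"auto"` picks explicit stepping unless the stable step
#'   is impractically small (thin tape / air voxels), then implicit
#'   backward Euler with a sparse Cholesky factorization.
#' @param safety fraction of the explicit stability bound used.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(flux, heatDuration, totalDuration,
                             ambient, initial = ambient, h = 10,
                             emissivity = 0, dt = NA_real_,
                             frameInterval = 1, method = "auto",
                             safety = 0.8) {
  new("SimulationConfig", flux = flux, heatDuration = heatDuration,
      totalDuration = totalDuration, ambient = ambient, initial = initial,
      h = h, emissivity = emissivity, dt = as.numeric(dt),
      frameInterval = frameInterval, method = method, safety = safety)
}

#' @describeIn simulationConfig the root-sample study conditions:
#'   0.0005 W mm^-2 for 10 s, 120 s total, 296.15 K, convection only.
#' @param ... overrides passed on to [simulationConfig()].
#' @export
rsaSimulationConfig <- function(...) {
  args <- utils::modifyList(
    list(flux = 0.0005, heatDuration = 10, totalDuration = 120,
         ambient = 296.15, h = 10, emissivity = 0),
    list(...))
  do.call(simulationConfig, args)
}

#' @describeIn simulationConfig the bubble-sample study conditions:
#'   0.0012 W mm^-2 for 30 s, 150 s total, 298.15 K, convection plus
#'   radiation from the taped surface.
#' @export
bubbleSimulationConfig <- function(...) {
  args <- utils::modifyList(
    list(flux = 0.0012, heatDuration = 30, totalDuration = 150,
         ambient = 298.15, h = 10, emissivity = 0.95, method = "implicit"),
    list(...))
  do.call(simulationConfig, args)
}

# face conductances (W/K) and voxel heat capacities (J/K), SI units
solverCoefficients <- function(sample) {
  p <- propertyGrids(sample)
  d <- dim(sample@materialId)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  dx <- sample@pitch * 1e-3
  dzm <- sample@dz * 1e-3
  dzArr <- array(rep(dzm, each = nx * ny), d)
  C <- p$rho * p$cp * dx * dx * dzArr

  Gx <- Gy <- Gz <- NULL
  if (nx > 1L) {
    k1 <- p$k[-nx, , , drop = FALSE]; k2 <- p$k[-1L, , , drop = FALSE]
    A <- dx * dzArr[-nx, , , drop = FALSE]
    Gx <- A / (dx / (2 * k1) + dx / (2 * k2))
  }
  if (ny > 1L) {
    k1 <- p$k[, -ny, , drop = FALSE]; k2 <- p$k[, -1L, , drop = FALSE]
    A <- dx * dzArr[, -ny, , drop = FALSE]
    Gy <- A / (dx / (2 * k1) + dx / (2 * k2))
  }
  if (nz > 1L) {
    k1 <- p$k[, , -nz, drop = FALSE]; k2 <- p$k[, , -1L, drop = FALSE]
    h1 <- dzArr[, , -nz, drop = FALSE]; h2 <- dzArr[, , -1L, drop = FALSE]
    Gz <- (dx * dx) / (h1 / (2 * k1) + h2 / (2 * k2))
  }
  list(C = C, Gx = Gx, Gy = Gy, Gz = Gz, topA = dx * dx, dims = d)
}

# largest stable explicit step (Gershgorin bound on the update operator)
stableStep <- function(co, h) {
  d <- co$dims
  S <- array(0, d)
  if (!is.null(co$Gx)) {
    S[-d[1L], , ] <- S[-d[1L], , ] + co$Gx
    S[-1L, , ]    <- S[-1L, , ] + co$Gx
  }
  if (!is.null(co$Gy)) {
    S[, -d[2L], ] <- S[, -d[2L], ] + co$Gy
    S[, -1L, ]    <- S[, -1L, ] + co$Gy
  }
  if (!is.null(co$Gz)) {
    S[, , -d[3L]] <- S[, , -d[3L]] + co$Gz
    S[, , -1L]    <- S[, , -1L] + co$Gz
  }
  S[, , 1L] <- S[, , 1L] + h * co$topA
  min(co$C / S)
}

#' Simulate the active-thermography transient
#'
#' Conservative finite-volume update on the voxel grid with harmonic-mean
#' interface conductances.  The top boundary receives the configured heat
#' flux during the heating phase and loses heat by convection
#' \eqn{h (T - T_\infty)} (plus \eqn{\epsilon \sigma (T^4 - T_\infty^4)}
#' when radiation is enabled) throughout; all other boundaries are
#' zero-flux.  Time stepping is either explicit forward-time
#' central-space, with the step auto-shrunk to the stability bound, or a
#' dimensionally split backward-Euler scheme (sequential implicit sweeps
#' along x, y and z, each a vectorized tridiagonal solve) when the grid
#' contains stiff voxels such as the 0.152 mm tape layer or air; the
#' split scheme is unconditionally stable and conserves energy exactly.
#' Surface frames (top-layer voxel-centre temperatures) are recorded
#' every `frameInterval` seconds, starting at t = 0.
#'
#' @param sample a [VoxelSample-class].
#' @param config a [SimulationConfig-class].
#' @param keepField if `TRUE`, the final 3-D temperature field is stored
#'   in the result's metadata (used by conservation checks).
#' @return A [SurfaceSequence-class]; its metadata carries the config,
#'   the in-plane pitch, the per-frame enthalpy history (J, relative to
#'   the initial state) and solver diagnostics.
#' @examples
#' s <- rasterizeRsaSample(rsaSampleSpec(2, pitch = 5, width = 65, height = 95),
#'                         rootArchitecture(data.frame()[0, ]))
#' \donttest{seq2 <- simulateSample(s, rsaSimulationConfig(totalDuration = 20))}
#' @export
simulateSample <- function(sample, config, keepField = FALSE) {
  stopifnot(is(sample, "VoxelSample"), is(config, "SimulationConfig"))
  validObject(config)
  if (prod(dim(sample@materialId)) == 0L) stop("empty sample")
  fi <- config@frameInterval
  if (abs(config@heatDuration / fi - round(config@heatDuration / fi)) > 1e-9 ||
      abs(config@totalDuration / fi - round(config@totalDuration / fi)) > 1e-9)
    stop("heating and total durations must be multiples of the frame interval")

  co <- solverCoefficients(sample)
  dtStable <- stableStep(co, config@h)
  method <- config@method
  if (method == "auto") method <- if (dtStable * config@safety >= 0.02) "explicit" else "implicit"

  if (method == "explicit") {
    dt <- config@safety * dtStable
    if (!is.na(config@dt)) {
      if (config@dt > dtStable) {
        message(sprintf("requested dt = %g s exceeds the stability bound %g s; shrinking",
                        config@dt, dtStable))
        dt <- config@safety * dtStable
      } else dt <- config@dt
    }
    nSub <- max(1L, as.integer(ceiling(fi / dt - 1e-9)))
    runSolver(sample, config, co, method, fi / nSub, nSub, keepField,
              diagnostics = list(method = "explicit", dtStable = dtStable))
  } else {
    dt <- if (is.na(config@dt)) min(0.5, fi) else min(config@dt, fi)
    nSub <- max(1L, as.integer(round(fi / dt)))
    runSolver(sample, config, co, method, fi / nSub, nSub, keepField,
              diagnostics = list(method = "implicit", dtStable = dtStable))
  }
}

runSolver <- function(sample, config, co, method, dt, nSub, keepField,
                      diagnostics) {
  d <- co$dims
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  Tinf <- config@ambient
  qW <- config@flux * 1e6                 # W mm^-2 -> W m^-2
  topA <- co$topA
  eps <- config@emissivity
  sig <- STEFAN_BOLTZMANN

  Tarr <- array(config@initial, d)
  frameTimes <- seq(0, config@totalDuration, by = config@frameInterval)
  nF <- length(frameTimes)
  frames <- array(NA_real_, c(nx, ny, nF))
  frames[, , 1L] <- Tarr[, , 1L]
  enthalpy <- numeric(nF)                 # J relative to the initial state
  Csum <- co$C

  implicitState <- NULL
  if (method == "implicit") implicitState <- implicitSplitSetup(co, config, dt)

  for (f in 2:nF) {
    tEnd <- frameTimes[f]
    for (s in seq_len(nSub)) {
      tNow <- tEnd - config@frameInterval + (s - 1L) * dt
      heating <- tNow < config@heatDuration - 1e-9
      Tarr <- if (method == "explicit")
        explicitStep(Tarr, co, dt, heating, qW, config@h, Tinf, eps, sig)
      else
        implicitStep(Tarr, implicitState, dt, heating, qW, config@h, Tinf,
                     eps, sig, topA)
    }
    if (any(!is.finite(Tarr)))
      stop(sprintf("non-finite temperature at t = %g s (method %s, dt %g s)",
                   tEnd, method, dt))
    frames[, , f] <- Tarr[, , 1L]
    enthalpy[f] <- sum(Csum * (Tarr - config@initial))
  }

  meta <- list(config = config, pitch = sample@pitch,
               sampleMeta = sample@meta, enthalpy = enthalpy,
               diagnostics = c(diagnostics, list(dt = dt, nSub = nSub)))
  if (keepField) meta$finalField <- Tarr
  new("SurfaceSequence", frames = frames, times = frameTimes, meta = meta)
}

explicitStep <- function(Tarr, co, dt, heating, qW, h, Tinf, eps, sig) {
  d <- co$dims
  net <- array(0, d)
  if (!is.null(co$Gx)) {
    Fx <- co$Gx * (Tarr[-1L, , , drop = FALSE] - Tarr[-d[1L], , , drop = FALSE])
    net[-d[1L], , ] <- net[-d[1L], , ] + Fx
    net[-1L, , ]    <- net[-1L, , ] - Fx
  }
  if (!is.null(co$Gy)) {
    Fy <- co$Gy * (Tarr[, -1L, , drop = FALSE] - Tarr[, -d[2L], , drop = FALSE])
    net[, -d[2L], ] <- net[, -d[2L], ] + Fy
    net[, -1L, ]    <- net[, -1L, ] - Fy
  }
  if (!is.null(co$Gz)) {
    Fz <- co$Gz * (Tarr[, , -1L, drop = FALSE] - Tarr[, , -d[3L], drop = FALSE])
    net[, , -d[3L]] <- net[, , -d[3L]] + Fz
    net[, , -1L]    <- net[, , -1L] - Fz
  }
  Ttop <- Tarr[, , 1L]
  bc <- -h * co$topA * (Ttop - Tinf)
  if (heating) bc <- bc + qW * co$topA
  if (eps > 0) bc <- bc - eps * sig * co$topA * (Ttop^4 - Tinf^4)
  net[, , 1L] <- net[, , 1L] + bc
  Tarr + dt * net / co$C
}

# Tridiagonal Thomas solve, vectorized across the rows of [m, n]
# matrices whose columns are successive positions along the solve axis
# (contiguous in memory): a (sub), b (diag), c (super), d (rhs);
# a[, 1] and c[, n] are ignored.  Returns the [m, n] solution.
triSolve <- function(a, b, c, d) {
  n <- ncol(b)
  if (n == 1L) return(d / b)
  cp <- b * 0; dp <- cp
  cp[, 1L] <- c[, 1L] / b[, 1L]
  dp[, 1L] <- d[, 1L] / b[, 1L]
  for (i in 2:n) {
    den <- b[, i] - a[, i] * cp[, i - 1L]
    cp[, i] <- c[, i] / den
    dp[, i] <- (d[, i] - a[, i] * dp[, i - 1L]) / den
  }
  x <- dp
  for (i in (n - 1L):1L) x[, i] <- dp[, i] - cp[, i] * x[, i + 1L]
  x
}

# Precompute the per-direction tridiagonal coefficients of the
# dimensionally split backward-Euler update (I + dt C^-1 A_dir).
# The solve axis is moved last (contiguous columns); top-surface
# convection is folded into the z-direction diagonal.
implicitSplitSetup <- function(co, config, dt) {
  d <- co$dims
  mk <- function(G, perm, n, hTop = 0) {
    m <- prod(d) / n
    Cd <- matrix(aperm(co$C, perm), m, n) / dt
    a <- matrix(0, m, n); cc <- matrix(0, m, n); b <- Cd
    if (n > 1L) {
      Gm <- matrix(aperm(G, perm), m, n - 1L)
      a[, 2:n] <- -Gm
      cc[, 1:(n - 1L)] <- -Gm
      b[, 1:(n - 1L)] <- b[, 1:(n - 1L)] + Gm
      b[, 2:n] <- b[, 2:n] + Gm
    }
    if (hTop > 0) b[, 1L] <- b[, 1L] + hTop
    list(a = a, b = b, cc = cc, Cd = Cd, perm = perm, n = n)
  }
  list(x = mk(co$Gx, c(2L, 3L, 1L), d[1L]),
       y = mk(co$Gy, c(1L, 3L, 2L), d[2L]),
       z = mk(co$Gz, c(1L, 2L, 3L), d[3L], hTop = config@h * co$topA),
       dims = d)
}

# one split step: sequential backward-Euler sweeps along x, y, z; the
# boundary sources (flux, convection sink, radiation) enter the z sweep
implicitStep <- function(Tarr, st, dt, heating, qW, h, Tinf, eps, sig, topA) {
  d <- st$dims
  sweep1 <- function(Tarr, dir, src = NULL) {
    s <- st[[dir]]
    Tm <- matrix(aperm(Tarr, s$perm), ncol = s$n)
    rhs <- s$Cd * Tm
    if (!is.null(src)) rhs[, 1L] <- rhs[, 1L] + src
    Tm <- triSolve(s$a, s$b, s$cc, rhs)
    aperm(array(Tm, d[s$perm]), order(s$perm))
  }
  Tarr <- sweep1(Tarr, "x")
  Tarr <- sweep1(Tarr, "y")
  Ttop <- as.numeric(Tarr[, , 1L])
  src <- rep(h * topA * Tinf, d[1L] * d[2L])
  if (heating) src <- src + qW * topA
  if (eps > 0) src <- src - eps * sig * topA * (Ttop^4 - Tinf^4)
  sweep1(Tarr, "z", src = src)
}

#' Total energy injected during the heating phase
#'
#' Returns flux x heated area x heating duration.  For the default
#' root-sample configuration (0.0005 W mm^-2 over 65 x 95 mm for 10 s)
#' this is 30.875 J.
#'
#' @param x an [RsaSampleSpec-class], [BubbleSampleSpec-class] or
#'   [VoxelSample-class] (defines the heated area).
#' @param config a [SimulationConfig-class] (defines flux and duration).
#' @return Energy in joules.
#' @examples
#' totalInputEnergy(rsaSampleSpec(2), rsaSimulationConfig())  # 30.875
#' @export
setGeneric("totalInputEnergy", function(x, config) standardGeneric("totalInputEnergy"))

#' @rdname totalInputEnergy
#' @export
setMethod("totalInputEnergy", "RsaSampleSpec", function(x, config) {
  config@flux * x@width * x@height * config@heatDuration
})

#' @rdname totalInputEnergy
#' @export
setMethod("totalInputEnergy", "BubbleSampleSpec", function(x, config) {
  config@flux * x@plateSide^2 * config@heatDuration
})

#' @rdname totalInputEnergy
#' @export
setMethod("totalInputEnergy", "VoxelSample", function(x, config) {
  d <- dim(x@materialId)
  config@flux * d[1L] * d[2L] * x@pitch^2 * config@heatDuration
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: q = %g W/mm^2 for %g s, total %g s, T0 = %g K, h = %g W/m^2/K, eps = %g, method = %s\n",
              object@flux, object@heatDuration, object@totalDuration,
              object@initial, object@h, object@emissivity, object@method))
})

setMethod("show", "SurfaceSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SurfaceSequence: %d frames of %d x %d pixels, t = %g..%g s\n",
              d[3L], d[1L], d[2L], min(object@times), max(object@times)))
  cat(sprintf("  temperature range %.3f..%.3f K\n",
              min(object@frames), max(object@frames)))
})

#' Accessors for SurfaceSequence
#'
#' @param x a [SurfaceSequence-class].
#' @param i frame index.
#' @return `frameTimes`: numeric timestamps (s); `nFrames`: frame count;
#'   `getFrame`: one 2-D temperature matrix (K); `enthalpyHistory`:
#'   per-frame total enthalpy change (J) relative to the initial state.
#' @name sequence-accessors
NULL

#' @rdname sequence-accessors
#' @export
frameTimes <- function(x) x@times
#' @rdname sequence-accessors
#' @export
nFrames <- function(x) dim(x@frames)[3L]
#' @rdname sequence-accessors
#' @export
getFrame <- function(x, i) {
  d <- dim(x@frames)
  matrix(x@frames[, , i], d[1L], d[2L])
}
#' @rdname sequence-accessors
#' @export
enthalpyHistory <- function(x) x@meta$enthalpy
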
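#' @import methods
#' @importFrom stats coef cor lm lm.fit predict rnorm sd var
NULL

#' Thermophysical material properties
#'
#' Holds the three constant thermophysical properties needed by the
#' conduction solver: density \eqn{\rho} (kg m^-3), thermal conductivity
#' \eqn{k} (W m^-1 K^-1) and specific heat capacity \eqn{c_p}
#' (J kg^-1 K^-1).  Thermal diffusivity \eqn{\alpha = k / (\rho c_p)} is
#' derived, never stored.
#'
#' @slot name character scalar, material label.
#' @slot density numeric scalar, kg m^-3, strictly positive.
#' @slot conductivity numeric scalar, W m^-1 K^-1, strictly positive.
#' @slot specificHeat numeric scalar, J kg^-1 K^-1, strictly positive.
#'
#' @export
setClass("MaterialProps",
  representation(
    name         = "character",
    density      = "numeric",
    conductivity = "numeric",
    specificHeat = "numeric"
  )
)

setValidity("MaterialProps", function(object) {
  msg <- character()
  for (s in c("density", "conductivity", "specificHeat")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single strictly positive finite number", s))
  }
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Planar root-system architecture
#'
#' A taproot architecture as a set of straight 2-D segments living in a
#' thin slab: each segment has start/end coordinates (mm, within the
#' sample footprint) and a diameter.  Primary segments default to 1 mm
#' diameter, secondary laterals to 0.5 mm.
#'
#' @slot segments data.frame with columns `x0`, `y0`, `x1`, `y1`
#'   (mm), `diameter` (mm) and `type` (`"primary"` or `"secondary"`).
#' @slot width,height numeric, footprint dimensions in mm.
#' @slot slabThickness numeric, thickness of the root slab in mm.
#'
#' @export
setClass("RootArchitecture",
  representation(
    segments      = "data.frame",
    width         = "numeric",
    height        = "numeric",
    slabThickness = "numeric"
  )
)

setValidity("RootArchitecture", function(object) {
  seg <- object@segments
  need <- c("x0", "y0", "x1", "y1", "diameter", "type")
  if (!all(need %in% names(seg)))
    return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
  if (nrow(seg)) {
    xy <- as.matrix(seg[, c("x0", "x1", "y0", "y1")])
    if (any(!is.finite(xy))) return("segment endpoints must be finite")
    r <- seg$diameter / 2
    if (any(seg$x0 - r < 0) || any(seg$x1 - r < 0) ||
        any(seg$x0 + r > object@width) || any(seg$x1 + r > object@width) ||
        any(seg$y0 - r < 0) || any(seg$y1 - r < 0) ||
        any(seg$y0 + r > object@height) || any(seg$y1 + r > object@height))
      return("a segment (including its radius) extends outside the sample footprint")
    if (any(seg$diameter <= 0)) return("segment diameters must be positive")
    if (!all(seg$type %in% c("primary", "secondary")))
      return("segment type must be 'primary' or 'secondary'")
  }
  TRUE
})

#' Specification of the root-system (RSA) sample
#'
#' Geometry of the layered sample: an acrylic cover on top, soil behind
#' it, and a thin root slab buried at `burialDepth` mm below the cover's
#' bottom face (the burial-depth convention used throughout).
#'
#' @slot width,height,totalDepth numeric, outer dimensions in mm
#'   (defaults 65 x 95 x 12).
#' @slot coverThickness numeric mm, acrylic cover thickness.
#' @slot burialDepth numeric mm, cover bottom to root top.
#' @slot slabThickness numeric mm, thickness of the root slab (1 mm).
#' @slot pitch numeric mm, in-plane voxel pitch.
#'
#' @export
setClass("RsaSampleSpec",
  representation(
    width          = "numeric",
    height         = "numeric",
    totalDepth     = "numeric",
    coverThickness = "numeric",
    burialDepth    = "numeric",
    slabThickness  = "numeric",
    pitch          = "numeric"
  )
)

setValidity("RsaSampleSpec", function(object) {
  msg <- character()
  for (s in c("width", "height", "totalDepth", "coverThickness",
              "burialDepth", "slabThickness", "pitch")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (!length(msg)) {
    if (object@coverThickness + object@burialDepth + object@slabThickness >
        object@totalDepth)
      msg <- c(msg, "cover + burial depth + slab thickness exceed the total depth")
    if (object@pitch > object@totalDepth)
      msg <- c(msg, "pitch is coarser than the sample depth")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of the plexiglass bubble sample
#'
#' Two stacked plexiglass plates under a thin layer of black electrical
#' tape, with a conical air void whose base (of the stated diameter) sits
#' on the plate-plate interface and whose apex points toward the heated
#' surface, `bubbleDepth` mm below it.
#'
#' @slot plateSide numeric mm, side of the square plates (40).
#' @slot plateThickness numeric mm, thickness of each plate (7).
#' @slot tapeThickness numeric mm, tape layer (0.152).
#' @slot bubbleDiameter numeric mm, cone base diameter (0 = no void).
#' @slot bubbleDepth numeric mm, surface to cone apex.
#' @slot pitch numeric mm, in-plane voxel pitch.
#'
#' @export
setClass("BubbleSampleSpec",
  representation(
    plateSide      = "numeric",
    plateThickness = "numeric",
    tapeThickness  = "numeric",
    bubbleDiameter = "numeric",
    bubbleDepth    = "numeric",
    pitch          = "numeric"
  )
)

setValidity("BubbleSampleSpec", function(object) {
  msg <- character()
  for (s in c("plateSide", "plateThickness", "tapeThickness", "pitch")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(object@bubbleDiameter) != 1L || object@bubbleDiameter < 0)
    msg <- c(msg, "'bubbleDiameter' must be a single non-negative number")
  if (length(object@bubbleDepth) != 1L || object@bubbleDepth < 0)
    msg <- c(msg, "'bubbleDepth' must be a single non-negative number")
  if (!length(msg) && object@bubbleDiameter > 0) {
    # apex must lie inside the upper plate; base diameter inside footprint
    if (object@bubbleDepth <= object@tapeThickness ||
        object@bubbleDepth >= object@tapeThickness + object@plateThickness)
      msg <- c(msg, "cone apex lies outside the upper plate")
    if (object@bubbleDiameter >= object@plateSide)
      msg <- c(msg, "bubble diameter exceeds the plate side")
  }
  if (length(msg)) msg else TRUE
})

#' Voxelized sample
#'
#' A 3-D material-ID grid with a per-material property table, uniform
#' in-plane pitch, a per-layer depth thickness vector (so material
#' interfaces in depth are honoured exactly), and the ground-truth mask of
#' the hidden structure projected onto the heated top surface.
#'
#' Axis convention: `x` runs across the sample width (array dim 1), `y`
#' down its height (dim 2), `z` from the heated top surface into the
#' sample (dim 3).  Physical coordinates are voxel centres in mm.
#'
#' @slot materialId integer 3-D array `[nx, ny, nz]`; values index rows
#'   of `materials`.
#' @slot materials data.frame with columns `name`, `density`,
#'   `conductivity`, `specificHeat` (row i = material id i).
#' @slot pitch numeric mm, in-plane (x and y) voxel pitch.
#' @slot dz numeric vector of length `nz`, layer thicknesses in mm.
#' @slot mask logical matrix `[nx, ny]`, top-surface projection of the
#'   hidden structure.
#' @slot meta list of provenance (building spec, architecture, ...).
#'
#' @export
setClass("VoxelSample",
  representation(
    materialId = "array",
    materials  = "data.frame",
    pitch      = "numeric",
    dz         = "numeric",
    mask       = "matrix",
    meta       = "list"
  )
)

setValidity("VoxelSample", function(object) {
  d <- dim(object@materialId)
  if (length(d) != 3L) return("materialId must be a 3-D array")
  if (length(object@dz) != d[3L]) return("length(dz) must equal dim 3 of materialId")
  if (any(object@dz <= 0)) return("all layer thicknesses must be positive")
  ids <- unique(as.integer(object@materialId))
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > nrow(object@materials)))
    return("every voxel must reference exactly one row of the material table")
  need <- c("name", "density", "conductivity", "specificHeat")
  if (!all(need %in% names(object@materials)))
    return("material table lacks name/density/conductivity/specificHeat")
  if (any(!is.finite(as.matrix(object@materials[need[-1]]))) ||
      any(as.matrix(object@materials[need[-1]]) <= 0))
    return("material properties must be positive and finite")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask dimensions must equal the top-surface frame dimensions")
  TRUE
})

#' Top-surface temperature sequence
#'
#' Ordered 2-D temperature frames (kelvin) of the heated surface with
#' strictly increasing timestamps, as an infrared camera above the sample
#' would record them.
#'
#' @slot frames numeric 3-D array `[nx, ny, nt]`, kelvin.
#' @slot times numeric vector of length `nt`, seconds.
#' @slot meta list: simulation config, sample provenance, enthalpy
#'   history, solver diagnostics.
#'
#' @export
setClass("SurfaceSequence",
  representation(
    frames = "array",
    times  = "numeric",
    meta   = "list"
  )
)

setValidity("SurfaceSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-D array [nx, ny, nt]")
  if (length(object@times) != d[3L]) return("length(times) must equal frame count")
  if (d[3L] > 1L && any(diff(object@times) <= 0))
    return("timestamps must be strictly increasing")
  if (any(!is.finite(object@frames))) return("all temperatures must be finite")
  TRUE
})

#' Samples-by-features temperature descriptor matrix
#'
#' Rows are (feature point, simulated model) pairs; columns are
#' cooling-phase temperatures sampled on a fixed time raster; each row
#' carries a numeric label (burial depth, or bubble diameter/depth).
#'
#' @slot features numeric matrix, rows = samples, columns = time samples.
#' @slot labels data.frame, one row per feature row (e.g. column `depth`).
#' @slot times numeric vector, sampling timestamps (s), one per column.
#' @slot meta list of provenance.
#'
#' @export
setClass("FeatureMatrix",
  representation(
    features = "matrix",
    labels   = "data.frame",
    times    = "numeric",
    meta     = "list"
  )
)

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@labels) != nrow(object@features))
    return("labels must have one row per feature row")
  if (length(object@times) != ncol(object@features))
    return("times must have one entry per feature column")
  if (any(!is.finite(object@features))) return("features must be finite")
  TRUE
})

#' Transient-simulation configuration
#'
#' Boundary conditions and time stepping for [simulateSample()]: a
#' constant heat flux on the top surface during the heating phase, natural
#' convection (and optionally radiation) from the top surface throughout,
#' all other faces perfectly insulated.
#'
#' @slot flux numeric, W mm^-2 applied to the top surface while heating.
#' @slot heatDuration,totalDuration numeric seconds.
#' @slot ambient,initial numeric kelvin.
#' @slot h numeric, convection coefficient W m^-2 K^-1.
#' @slot emissivity numeric in `[0, 1]`; 0 disables radiation.
#' @slot dt numeric seconds; `NA` = choose automatically.
#' @slot frameInterval numeric seconds between recorded frames.
#' @slot method character: `"auto"`, `"explicit"` or `"implicit"`.
#' @slot safety numeric in (0, 1], fraction of the explicit stability
#'   bound actually used.
#'
#' @export
setClass("SimulationConfig",
  representation(
    flux          = "numeric",
    heatDuration  = "numeric",
    totalDuration = "numeric",
    ambient       = "numeric",
    initial       = "numeric",
    h             = "numeric",
    emissivity    = "numeric",
    dt            = "numeric",
    frameInterval = "numeric",
    method        = "character",
    safety        = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@flux < 0) msg <- c(msg, "flux must be non-negative")
  if (object@heatDuration > object@totalDuration)
    msg <- c(msg, "heating duration exceeds total duration")
  if (object@heatDuration < 0 || object@totalDuration <= 0)
    msg <- c(msg, "durations must be positive")
  if (!object@method %in% c("auto", "explicit", "implicit"))
    msg <- c(msg, "method must be 'auto', 'explicit' or 'implicit'")
  if (object@emissivity < 0 || object@emissivity > 1)
    msg <- c(msg, "emissivity must be in [0, 1]")
  if (object@h < 0) msg <- c(msg, "h must be non-negative")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive")
  if (!is.na(object@dt) && object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@safety <= 0 || object@safety > 1)
    msg <- c(msg, "safety must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Line-scan detection result
#'
#' Pixel coordinates flagged as root region by the line-scan algorithm,
#' together with the equivalent binary map and the provenance of the run.
#'
#' @slot coords integer matrix with columns `x`, `y` (pixel indices,
#'   1-based), one row per flagged pixel.
#' @slot map logical matrix `[nx, ny]`; `map[x, y]` is `TRUE` iff
#'   `(x, y)` is in `coords`.
#' @slot provenance list: smoothing window, frames used, scan directions.
#'
#' @export
setClass("DetectionResult",
  representation(
    coords     = "matrix",
    map        = "matrix",
    provenance = "list"
  )
)

setValidity("DetectionResult", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns (x, y)")
  n <- nrow(object@coords)
  if (n) {
    if (any(object@coords[, 1L] < 1L) || any(object@coords[, 1L] > nrow(object@map)) ||
        any(object@coords[, 2L] < 1L) || any(object@coords[, 2L] > ncol(object@map)))
      return("coords must lie inside the frame domain")
  }
  if (sum(object@map) != n)
    return("binary map and coordinate set must be in bijection")
  if (n && !all(object@map[object@coords]))
    return("binary map and coordinate set disagree")
  TRUE
})
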
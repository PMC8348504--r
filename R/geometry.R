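#' Create a root-sample specification
#'
#' Geometry of the layered root-system sample: acrylic cover in front,
#' soil behind, and a thin root slab whose top face sits `burialDepth` mm
#' below the bottom of the cover (the burial-depth convention used
#' throughout).
#'
#' @param burialDepth mm, distance from the cover's bottom face to the top
#'   of the root slab.
#' @param coverThickness mm (default 2; 3 and 4 are used in cover sweeps).
#' @param pitch mm, in-plane voxel pitch.
#' @param width,height,totalDepth mm, outer dimensions.
#' @param slabThickness mm, thickness of the root slab.
#' @return An [RsaSampleSpec-class] object.
#' @examples
#' rsaSampleSpec(burialDepth = 2)
#' @export
rsaSampleSpec <- function(burialDepth, coverThickness = 2, pitch = 1,
                          width = 65, height = 95, totalDepth = 12,
                          slabThickness = 1) {
  new("RsaSampleSpec", width = width, height = height, totalDepth = totalDepth,
      coverThickness = coverThickness, burialDepth = burialDepth,
      slabThickness = slabThickness, pitch = pitch)
}

#' Create a bubble-sample specification
#'
#' Two stacked plexiglass plates under black electrical tape with a
#' conical air void: the cone base (diameter `bubbleDiameter`) lies on the
#' plate-plate interface, the apex points toward the heated surface and
#' sits `bubbleDepth` mm below it.
#'
#' @param bubbleDiameter mm, base diameter of the conical void (0 = none).
#' @param bubbleDepth mm, heated surface to cone apex.
#' @param pitch mm, in-plane voxel pitch.
#' @param plateSide,plateThickness,tapeThickness mm.
#' @return A [BubbleSampleSpec-class] object.
#' @examples
#' bubbleSampleSpec(5.95, 4.76)
#' @export
bubbleSampleSpec <- function(bubbleDiameter, bubbleDepth, pitch = 0.5,
                             plateSide = 40, plateThickness = 7,
                             tapeThickness = 0.152) {
  new("BubbleSampleSpec", plateSide = plateSide, plateThickness = plateThickness,
      tapeThickness = tapeThickness, bubbleDiameter = bubbleDiameter,
      bubbleDepth = bubbleDepth, pitch = pitch)
}

#' Construct a RootArchitecture from explicit segments
#'
#' @param segments data.frame with columns `x0`, `y0`, `x1`, `y1`,
#'   `diameter` (mm) and `type` ("primary"/"secondary").
#' @param width,height mm, footprint the architecture must fit in.
#' @param slabThickness mm.
#' @return A [RootArchitecture-class] object; segments outside the
#'   footprint are rejected with a diagnostic.
#' @export
rootArchitecture <- function(segments, width = 65, height = 95,
                             slabThickness = 1) {
  new("RootArchitecture", segments = segments, width = width, height = height,
      slabThickness = slabThickness)
}

#' Build a parametric taproot architecture
#'
#' Procedural stand-in for a sugar-beet taproot: one central vertical
#' primary root, a configurable number of lateral primary branches leaving
#' it at alternating sides, and short secondary laterals spread along the
#' primaries.  Primary segments are 1 mm in diameter, secondaries 0.5 mm.
#' Deterministic for a fixed seed; any segment that would leave the
#' footprint is shortened to fit (never silently dropped) and the
#' constructor still rejects architectures that violate the footprint.
#'
#' @param width,height mm, sample footprint (default 65 x 95).
#' @param primaryBranches number of lateral primary branches (default 3).
#' @param secondaryCount number of secondary laterals (default 10).
#' @param primaryDiameter,secondaryDiameter mm (defaults 1 and 0.5).
#' @param slabThickness mm.
#' @param seed integer, controls the angle/length jitter.
#' @return A [RootArchitecture-class] object.
#' @examples
#' arch <- buildTaprootArchitecture()
#' nrow(arch@segments)
#' @export
buildTaprootArchitecture <- function(width = 65, height = 95,
                                     primaryBranches = 3L, secondaryCount = 10L,
                                     primaryDiameter = 1, secondaryDiameter = 0.5,
                                     slabThickness = 1, seed = 1L) {
  margin <- 2
  cx <- width / 2
  y0 <- 8
  y1 <- height - 8
  segs <- data.frame(x0 = cx, y0 = y0, x1 = cx, y1 = y1,
                     diameter = primaryDiameter, type = "primary",
                     stringsAsFactors = FALSE)

  clipLen <- function(px, py, ang, len) {
    # shorten so the endpoint stays 'margin' clear of the footprint
    dx <- sin(ang); dy <- cos(ang)
    lim <- len
    if (dx > 0) lim <- min(lim, (width - margin - px) / dx)
    if (dx < 0) lim <- min(lim, (margin - px) / dx)
    if (dy > 0) lim <- min(lim, (height - margin - py) / dy)
    if (dy < 0) lim <- min(lim, (margin - py) / dy)
    max(lim, 0)
  }

  withr::with_seed(as.integer(seed), {
    if (primaryBranches > 0L) {
      at <- seq(0.22, 0.68, length.out = primaryBranches)
      for (i in seq_len(primaryBranches)) {
        py <- y0 + at[i] * (y1 - y0)
        side <- if (i %% 2L == 1L) 1 else -1
        ang <- side * (pi / 4 + stats::runif(1, -0.2, 0.2))  # from vertical
        len <- clipLen(cx, py, ang, stats::runif(1, 20, 26))
        segs <- rbind(segs, data.frame(
          x0 = cx, y0 = py, x1 = cx + len * sin(ang), y1 = py + len * cos(ang),
          diameter = primaryDiameter, type = "primary", stringsAsFactors = FALSE))
      }
    }
    if (secondaryCount > 0L) {
      prim <- segs[segs$type == "primary", ]
      for (j in seq_len(secondaryCount)) {
        k <- 1L + (j - 1L) %% nrow(prim)          # cycle over primaries
        f <- stats::runif(1, 0.15, 0.85)
        px <- prim$x0[k] + f * (prim$x1[k] - prim$x0[k])
        py <- prim$y0[k] + f * (prim$y1[k] - prim$y0[k])
        ang <- stats::runif(1, 0, 2 * pi)
        len <- clipLen(px, py, ang, stats::runif(1, 4, 8))
        if (len < 1) { ang <- ang + pi; len <- clipLen(px, py, ang, 6) }
        segs <- rbind(segs, data.frame(
          x0 = px, y0 = py, x1 = px + len * sin(ang), y1 = py + len * cos(ang),
          diameter = secondaryDiameter, type = "secondary",
          stringsAsFactors = FALSE))
      }
    }
  })
  rootArchitecture(segs, width = width, height = height,
                   slabThickness = slabThickness)
}

# depth layering: subdivide [0, total] into layers no thicker than pitch,
# snapping layer boundaries to every material interface in `breaks`
zLayers <- function(totalDepth, pitch, breaks = numeric()) {
  b <- sort(unique(c(0, breaks[breaks > 1e-9 & breaks < totalDepth - 1e-9],
                     totalDepth)))
  dz <- numeric()
  for (i in seq_len(length(b) - 1L)) {
    len <- b[i + 1L] - b[i]
    n <- max(1L, ceiling(len / pitch - 1e-9))
    dz <- c(dz, rep(len / n, n))
  }
  dz
}

# in-plane voxel count for one dimension, with a rounding policy that
# tolerates pitches dividing the dimension only approximately
planeCount <- function(len, pitch) {
  n <- round(len / pitch)
  if (n < 1L || abs(n * pitch - len) > 0.26 * pitch)
    stop(sprintf("pitch %g mm does not divide dimension %g mm within the rounding policy",
                 pitch, len))
  as.integer(n)
}

# squared distance from points (px, py) to segment (x0,y0)-(x1,y1)
segDist2 <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-12) return((px - x0)^2 + (py - y0)^2)
  t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / L2))
  (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
}

# rasterize architecture segments onto the xy grid (centre-point membership)
rasterizeSegments <- function(segments, xc, yc) {
  nx <- length(xc); ny <- length(yc)
  px <- rep(xc, times = ny)
  py <- rep(yc, each = nx)
  hit <- rep(FALSE, nx * ny)
  for (i in seq_len(nrow(segments))) {
    r <- segments$diameter[i] / 2
    d2 <- segDist2(px, py, segments$x0[i], segments$y0[i],
                   segments$x1[i], segments$y1[i])
    hit <- hit | (d2 <= r * r + 1e-12)
  }
  matrix(hit, nx, ny)
}

#' Rasterize the root-system sample
#'
#' Builds the voxel grid for an [RsaSampleSpec-class]: acrylic cover
#' layers in front, soil behind, and the root slab embedded at the burial
#' depth.  Depth layering is snapped to the cover and slab interfaces, so
#' burial depths that are not multiples of the pitch (e.g. 4.5 mm at 1 mm
#' pitch) are honoured exactly.  The ground-truth mask is the top-down
#' projection of all root voxels.
#'
#' @param spec an [RsaSampleSpec-class].
#' @param arch a [RootArchitecture-class] (may have zero segments).
#' @param materials named list with `soil`, `root`, `acrylic` entries
#'   (default [defaultMaterials()]).
#' @return A [VoxelSample-class].
#' @examples
#' s <- rasterizeRsaSample(rsaSampleSpec(2), buildTaprootArchitecture())
#' materialVolumes(s)
#' @export
rasterizeRsaSample <- function(spec, arch, materials = defaultMaterials()) {
  stopifnot(is(spec, "RsaSampleSpec"), is(arch, "RootArchitecture"))
  validObject(spec); validObject(arch)
  mats <- materials[c("soil", "root", "acrylic")]
  nx <- planeCount(spec@width, spec@pitch)
  ny <- planeCount(spec@height, spec@pitch)
  xc <- (seq_len(nx) - 0.5) * spec@pitch
  yc <- (seq_len(ny) - 0.5) * spec@pitch

  slabTop <- spec@coverThickness + spec@burialDepth
  dz <- zLayers(spec@totalDepth, spec@pitch,
                breaks = c(spec@coverThickness, slabTop,
                           slabTop + spec@slabThickness))
  zc <- cumsum(dz) - dz / 2

  if (nrow(arch@segments) &&
      spec@pitch > min(arch@segments$diameter) + 1e-9)
    warning("voxel pitch is coarser than the thinnest root diameter; ",
            "secondary roots may vanish from the rasterization")

  id <- array(1L, dim = c(nx, ny, length(dz)))          # 1 = soil
  id[, , zc < spec@coverThickness] <- 3L                # 3 = acrylic cover
  inSlab <- zc >= slabTop & zc < slabTop + spec@slabThickness
  rootXY <- if (nrow(arch@segments)) rasterizeSegments(arch@segments, xc, yc)
            else matrix(FALSE, nx, ny)
  for (k in which(inSlab)) id[, , k][rootXY] <- 2L      # 2 = root

  new("VoxelSample", materialId = id, materials = materialTable(mats),
      pitch = spec@pitch, dz = dz, mask = rootXY,
      meta = list(spec = spec, architecture = arch, kind = "rsa"))
}

#' Build the plexiglass bubble sample
#'
#' Voxelizes two stacked plexiglass plates under a thin tape layer with a
#' centred conical air void (apex toward the surface at the specified
#' depth, base of the specified diameter on the plate interface).  The
#' tape occupies its own thin depth layer; the mask is the projected void.
#'
#' @param spec a [BubbleSampleSpec-class].
#' @param materials named list with `plexiglass`, `air`, `tape` entries.
#' @return A [VoxelSample-class].
#' @examples
#' s <- buildBubbleSample(bubbleSampleSpec(5.95, 4.76, pitch = 1))
#' sum(truthMask(s))
#' @export
buildBubbleSample <- function(spec, materials = defaultMaterials()) {
  stopifnot(is(spec, "BubbleSampleSpec"))
  validObject(spec)
  mats <- materials[c("plexiglass", "air", "tape")]
  nx <- planeCount(spec@plateSide, spec@pitch)
  ny <- nx
  xc <- (seq_len(nx) - 0.5) * spec@pitch
  yc <- xc
  total <- spec@tapeThickness + 2 * spec@plateThickness
  iface <- spec@tapeThickness + spec@plateThickness     # plate-plate interface
  dz <- zLayers(total, spec@pitch, breaks = c(spec@tapeThickness, iface))
  zc <- cumsum(dz) - dz / 2

  id <- array(1L, dim = c(nx, ny, length(dz)))          # 1 = plexiglass
  id[, , zc < spec@tapeThickness] <- 3L                 # 3 = tape

  mask <- matrix(FALSE, nx, ny)
  if (spec@bubbleDiameter > 0) {
    R <- spec@bubbleDiameter / 2
    apex <- spec@bubbleDepth
    cx <- spec@plateSide / 2
    d2 <- outer((xc - cx)^2, (yc - cx)^2, "+")          # squared xy distance
    for (k in which(zc > apex & zc <= iface)) {
      r <- R * (zc[k] - apex) / (iface - apex)
      hit <- d2 <= r * r + 1e-12
      layer <- id[, , k]; layer[hit] <- 2L; id[, , k] <- layer   # 2 = air
      mask <- mask | hit
    }
  }

  new("VoxelSample", materialId = id, materials = materialTable(mats),
      pitch = spec@pitch, dz = dz, mask = mask,
      meta = list(spec = spec, kind = "bubble"))
}

#' Accessors for VoxelSample
#'
#' @param x a [VoxelSample-class].
#' @return `materialId`: the integer 3-D grid; `voxelPitch`: in-plane
#'   pitch (mm); `zThickness`: per-layer depth thicknesses (mm);
#'   `truthMask`: logical top-surface mask of the hidden structure.
#' @name voxel-accessors
NULL

#' @rdname voxel-accessors
#' @export
materialId <- function(x) x@materialId
#' @rdname voxel-accessors
#' @export
voxelPitch <- function(x) x@pitch
#' @rdname voxel-accessors
#' @export
zThickness <- function(x) x@dz
#' @rdname voxel-accessors
#' @export
truthMask <- function(x) x@mask

#' Material volumes of a voxel sample
#'
#' @param sample a [VoxelSample-class].
#' @return Named numeric vector of per-material volumes in mm^3 (voxel
#'   counting); their sum equals the sample volume exactly.
#' @export
materialVolumes <- function(sample) {
  stopifnot(is(sample, "VoxelSample"))
  d <- dim(sample@materialId)
  vLayer <- sample@pitch^2 * sample@dz                 # mm^3 per voxel per layer
  out <- numeric(nrow(sample@materials))
  for (k in seq_len(d[3L])) {
    tab <- tabulate(sample@materialId[, , k], nbins = length(out))
    out <- out + tab * vLayer[k]
  }
  names(out) <- sample@materials$name
  out
}

# per-voxel property arrays in SI units, used by the solver
propertyGrids <- function(sample) {
  id <- sample@materialId
  list(rho = array(sample@materials$density[id], dim(id)),
       k   = array(sample@materials$conductivity[id], dim(id)),
       cp  = array(sample@materials$specificHeat[id], dim(id)))
}

setMethod("show", "VoxelSample", function(object) {
  d <- dim(object@materialId)
  cat(sprintf("VoxelSample: %d x %d x %d voxels, pitch %g mm, depth %g mm\n",
              d[1], d[2], d[3], object@pitch, sum(object@dz)))
  v <- materialVolumes(object)
  cat("  volumes (mm^3):", paste(sprintf("%s=%.4g", names(v), v), collapse = ", "), "\n")
  cat(sprintf("  hidden-structure mask: %d of %d surface pixels\n",
              sum(object@mask), prod(d[1:2])))
})

setMethod("show", "RootArchitecture", function(object) {
  cat(sprintf("RootArchitecture: %d primary + %d secondary segments in %g x %g mm\n",
              sum(object@segments$type == "primary"),
              sum(object@segments$type == "secondary"),
              object@width, object@height))
})

setMethod("show", "RsaSampleSpec", function(object) {
  cat(sprintf("RsaSampleSpec: %g x %g x %g mm, cover %g mm, burial %g mm, slab %g mm, pitch %g mm\n",
              object@width, object@height, object@totalDepth,
              object@coverThickness, object@burialDepth,
              object@slabThickness, object@pitch))
})

setMethod("show", "BubbleSampleSpec", function(object) {
  cat(sprintf("BubbleSampleSpec: %g x %g x (2 x %g + %g) mm, bubble D %g mm at depth %g mm, pitch %g mm\n",
              object@plateSide, object@plateSide, object@plateThickness,
              object@tapeThickness, object@bubbleDiameter,
              object@bubbleDepth, object@pitch))
})
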
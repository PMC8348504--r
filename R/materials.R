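#' Create a MaterialProps object
#'
#' @param name material label.
#' @param density kg m^-3.
#' @param conductivity W m^-1 K^-1.
#' @param specificHeat J kg^-1 K^-1.
#' @return A [MaterialProps-class] object.
#' @examples
#' soil <- materialProps("soil", 1300, 0.35, 830)
#' diffusivity(soil)   # m^2 s^-1
#' @export
materialProps <- function(name, density, conductivity, specificHeat) {
  new("MaterialProps", name = as.character(name), density = as.numeric(density),
      conductivity = as.numeric(conductivity), specificHeat = as.numeric(specificHeat))
}

#' @describeIn materialProps thermal diffusivity k / (rho * cp), m^2 s^-1.
#' @param x a `MaterialProps` object.
#' @export
diffusivity <- function(x) {
  stopifnot(is(x, "MaterialProps"))
  x@conductivity / (x@density * x@specificHeat)
}

#' Accessors for MaterialProps
#'
#' @param x a [MaterialProps-class] object.
#' @return the corresponding numeric property.
#' @name material-accessors
NULL

#' @rdname material-accessors
#' @export
density <- function(x) x@density
#' @rdname material-accessors
#' @export
conductivity <- function(x) x@conductivity
#' @rdname material-accessors
#' @export
specificHeat <- function(x) x@specificHeat

setMethod("show", "MaterialProps", function(object) {
  cat(sprintf("MaterialProps '%s': rho = %g kg/m^3, k = %g W/m/K, cp = %g J/kg/K (alpha = %.3g m^2/s)\n",
              object@name, object@density, object@conductivity,
              object@specificHeat, diffusivity(object)))
})

#' Default material library
#'
#' Constant thermophysical properties used throughout: soil, sugar-beet
#' root and acrylic glass for the root-system sample; plexiglass, air (25
#' degC, 1 atm) and black electrical tape for the bubble sample.  The tape
#' values are typical vinyl-tape figures chosen here (no literature value
#' is pinned for them); all entries can be overridden by passing modified
#' objects to the sample builders.
#'
#' @return Named list of [MaterialProps-class] objects with elements
#'   `soil`, `root`, `acrylic`, `plexiglass`, `air`, `tape`.
#' @examples
#' defaultMaterials()$root
#' @export
defaultMaterials <- function() {
  list(
    soil       = materialProps("soil",       1300,   0.35,    830),
    root       = materialProps("root",       1169.9, 0.427,   3546.4),
    acrylic    = materialProps("acrylic",    1150,   0.17,    1470),
    plexiglass = materialProps("plexiglass", 1185,   0.1934,  1359),
    air        = materialProps("air",        1.184,  0.02551, 1007),
    tape       = materialProps("tape",       1350,   0.19,    1350)
  )
}

# material list -> data.frame table (row i = id i)
materialTable <- function(mats) {
  data.frame(
    name         = vapply(mats, function(m) m@name, character(1)),
    density      = vapply(mats, density, numeric(1)),
    conductivity = vapply(mats, conductivity, numeric(1)),
    specificHeat = vapply(mats, specificHeat, numeric(1)),
    row.names = NULL
  )
}
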
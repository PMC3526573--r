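## Analytical perfusion physics for a parallel-plate culture chamber.
## All quantities are stored in SI; constructors accept the bench units
## the chamber is usually described in (mm, um, ul/h).

#' Construct chamber geometry
#'
#' @param width chamber width across the flow, in mm (default 13).
#' @param length chamber length along the flow, in mm (default 4).
#' @param height chamber gap height, in um (default 450).
#' @param recess flow-layer elevation above the culture plane, in um
#'   (default 120; informational).
#' @return a \linkS4class{ChamberGeometry} (slots in metres).
#' @export
chamberGeometry <- function(width = 13, length = 4, height = 450,
                            recess = 120) {
  new("ChamberGeometry", width = width * 1e-3, length = length * 1e-3,
      height = height * 1e-6, recess = recess * 1e-6)
}

#' Construct fluid properties
#'
#' @param viscosity dynamic viscosity in Pa s (default 6.96e-4, water at
#'   37 C).
#' @param density density in kg m^-3 (default 993.2).
#' @return a \linkS4class{FluidProperties}.
#' @export
fluidProperties <- function(viscosity = 6.96e-4, density = 993.2) {
  new("FluidProperties", viscosity = viscosity, density = density)
}

#' Construct perfusion conditions
#'
#' @param flowRate volumetric flow rate in ul/h (default 300).
#' @param geometry a \linkS4class{ChamberGeometry}.
#' @param fluid a \linkS4class{FluidProperties}.
#' @return a \linkS4class{PerfusionConditions}.
#' @export
perfusionConditions <- function(flowRate = 300,
                                geometry = chamberGeometry(),
                                fluid = fluidProperties()) {
  new("PerfusionConditions", flowRate = ulPerHourToSI(flowRate),
      geometry = geometry, fluid = fluid)
}

#' Flow-rate unit round trip
#'
#' @param x flow rate in ul/h (\code{ulPerHourToSI}) or m^3/s
#'   (\code{siToUlPerHour}).
#' @return the converted value.
#' @export
ulPerHourToSI <- function(x) x * 1e-9 / 3600

#' @rdname ulPerHourToSI
#' @export
siToUlPerHour <- function(x) x * 3600 / 1e-9

#' Wall shear stress between infinite parallel plates
#'
#' tau_w = 6 mu Q / (h^2 w): the shear stress exerted on the culture
#' surface by fully developed laminar flow through a rectangular gap of
#' height h and width w. With the default conditions (300 ul/h through a
#' 13 mm x 450 um gap, mu = 6.96e-4 Pa s) this evaluates to about
#' 1.3e-4 Pa.
#'
#' @param cond a \linkS4class{PerfusionConditions}.
#' @return wall shear stress in Pa.
#' @export
wallShear <- function(cond) {
  stopifnot(is(cond, "PerfusionConditions"))
  h <- cond@geometry@height; w <- cond@geometry@width
  if (h <= 0 || w <= 0) stop("chamber height and width must be positive")
  6 * cond@fluid@viscosity * cond@flowRate / (h^2 * w)
}

#' Shear stress at a height above the culture plane
#'
#' The plane-Poiseuille velocity profile gives a linearly decaying shear
#' magnitude tau(z) = tau_w (1 - 2 z / h): equal to the wall value at the
#' surface and zero at mid-gap. Returned as a magnitude.
#'
#' @param cond a \linkS4class{PerfusionConditions}.
#' @param z height above the culture plane, in um; must lie in [0, h].
#' @return shear stress magnitude in Pa.
#' @export
shearAtHeight <- function(cond, z) {
  stopifnot(is(cond, "PerfusionConditions"))
  zm <- z * 1e-6
  h <- cond@geometry@height
  if (any(zm < 0 | zm > h))
    stop("z must lie between 0 and the chamber height")
  abs(wallShear(cond) * (1 - 2 * zm / h))
}

#' Mean residence time of medium in the chamber
#'
#' Chamber volume over volumetric flow rate; about 4.7 min under the
#' default conditions.
#'
#' @param cond a \linkS4class{PerfusionConditions}.
#' @return residence time in minutes.
#' @export
residenceTime <- function(cond) {
  stopifnot(is(cond, "PerfusionConditions"))
  if (cond@flowRate <= 0) stop("residence time requires a positive flow rate")
  vol <- cond@geometry@width * cond@geometry@length * cond@geometry@height
  vol / cond@flowRate / 60
}

#' Culture area of the chamber
#'
#' @param geom a \linkS4class{ChamberGeometry}.
#' @return area in cm^2 (0.52 for the default 13 mm x 4 mm chamber).
#' @export
cultureArea <- function(geom) {
  stopifnot(is(geom, "ChamberGeometry"))
  geom@width * geom@length * 1e4  # m^2 -> cm^2
}

#' Media exchange rate per culture area
#'
#' Daily perfused volume normalised by the culture area; 300 ul/h over
#' 0.52 cm^2 gives 13.8 ml/day/cm^2.
#'
#' @param cond a \linkS4class{PerfusionConditions}.
#' @return exchange rate in ml per day per cm^2.
#' @export
mediaExchangeRate <- function(cond) {
  stopifnot(is(cond, "PerfusionConditions"))
  areaCm2 <- cultureArea(cond@geometry)
  if (areaCm2 <= 0) stop("culture area must be positive")
  mlPerDay <- cond@flowRate * 86400 * 1e6  # m^3/s -> ml/day
  mlPerDay / areaCm2
}

#' Seeding density over the chamber area
#'
#' @param geom a \linkS4class{ChamberGeometry}.
#' @param cells number of cells seeded.
#' @return density in cells per cm^2 (15,000 cells over the default
#'   chamber give about 28,800).
#' @export
seedingDensity <- function(geom, cells) {
  cells / cultureArea(geom)
}

#' Full perfusion report
#'
#' @param cond a \linkS4class{PerfusionConditions}.
#' @param z report height for the above-surface shear, in um (default
#'   15).
#' @return named list: wall_shear_Pa, shear_at_z_Pa, residence_min,
#'   exchange_ml_day_cm2, area_cm2.
#' @export
perfusionReport <- function(cond, z = 15) {
  list(wall_shear_Pa = wallShear(cond),
       shear_at_z_Pa = shearAtHeight(cond, z),
       residence_min = residenceTime(cond),
       exchange_ml_day_cm2 = mediaExchangeRate(cond),
       area_cm2 = cultureArea(cond@geometry))
}
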
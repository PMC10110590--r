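#' Geometry of one arterial segment
#'
#' A segment is a circular tube characterized by its length, internal
#' diameter and (for curved vessels) the radius of curvature of its bend,
#' together with the resistance formula it is assigned:
#' `"tortuous"` for long/curved vessels, where secondary (transverse-vortex)
#' flow adds dissipation, or `"entrance"` for short vessels, where the
#' velocity profile never fully develops.
#'
#' @param length segment length (> 0).
#' @param diameter internal diameter (> 0).
#' @param curvature_radius bend curvature radius (> 0); irrelevant for the
#'   entrance formula but retained as an anatomical attribute.
#' @param formula `"tortuous"` or `"entrance"`.
#' @param units `"mm"` (default, the anatomical dialect) or `"m"`.
#'   Dimensions are stored in metres internally.
#' @return An object of class `cow_geometry` with fields in metres.
#' @examples
#' segment_geometry(250, 4, 10, "tortuous")          # an ICA
#' segment_geometry(5, 1.2, 40, "entrance")          # an ACoA
#' @export
segment_geometry <- function(length, diameter, curvature_radius,
                             formula = c("tortuous", "entrance"),
                             units = c("mm", "m")) {
  formula <- match.arg(tolower(formula), c("tortuous", "entrance"))
  units <- match.arg(units)
  v <- c(length = length, diameter = diameter, curvature = curvature_radius)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v <= 0))
    stop("length, diameter and curvature_radius must all be positive",
         call. = FALSE)
  k <- if (units == "mm") 1e-3 else 1
  structure(list(length = length * k, diameter = diameter * k,
                 curvature_radius = curvature_radius * k, formula = formula),
            class = "cow_geometry")
}

#' @export
print.cow_geometry <- function(x, ...) {
  cat(sprintf("<segment geometry> L = %.2f mm, d = %.2f mm, a_k = %.2f mm, %s formula\n",
              x$length * 1e3, x$diameter * 1e3, x$curvature_radius * 1e3,
              x$formula))
  invisible(x)
}

# vectorized workers used by the solver (SI units throughout)
.hp <- function(length, diameter, mu) 128 * mu * length / (pi * diameter^4)
.re_diam <- function(flow, diameter, rho, mu) 4 * rho * abs(flow) / (pi * mu * diameter)
.ratio_tortuous <- function(re, diameter, curvature)
  0.526 + sqrt(0.225 + 0.022 * sqrt(diameter / curvature) * re)
.ratio_entrance <- function(re, diameter, length)
  1 + 0.044 * (diameter / length) * re

#' Hagen-Poiseuille resistance of a segment
#'
#' Laminar fully developed flow resistance of a straight circular tube,
#' \eqn{R_{HP} = 128\,\mu L / (\pi d^4)}. This is the linear baseline every
#' nonlinear correction multiplies.
#'
#' @param geom a [segment_geometry()].
#' @param fluid a [fluid_properties()].
#' @return resistance in Pa·s/m\eqn{^3}.
#' @examples
#' ica <- segment_geometry(250, 4, 10, "tortuous")
#' hagen_poiseuille_resistance(ica, fluid_properties())  # 1.3926e8
#' @export
hagen_poiseuille_resistance <- function(geom, fluid = fluid_properties()) {
  stopifnot(inherits(geom, "cow_geometry"), inherits(fluid, "cow_fluid"))
  .hp(geom$length, geom$diameter, fluid$viscosity)
}

#' Reynolds number of the flow in a segment
#'
#' Based on the mean velocity and the vessel diameter:
#' \eqn{Re = \rho \bar v d / \mu = 4 \rho |Q| / (\pi \mu d)}. The magnitude
#' of the flow is used, so the value is independent of the sign convention;
#' zero flow gives Re = 0.
#'
#' @param flow volumetric flow, m\eqn{^3}/s (may be negative; vectorized).
#' @param geom a [segment_geometry()].
#' @param fluid a [fluid_properties()].
#' @return dimensionless Reynolds number, same length as `flow`.
#' @examples
#' ica <- segment_geometry(250, 4, 10, "tortuous")
#' reynolds_number(4.55e-6, ica, fluid_properties())  # ~434.5
#' @export
reynolds_number <- function(flow, geom, fluid = fluid_properties()) {
  stopifnot(inherits(geom, "cow_geometry"), inherits(fluid, "cow_fluid"),
            is.numeric(flow))
  .re_diam(flow, geom$diameter, fluid$density, fluid$viscosity)
}

#' Resistance correction for tortuous (curved) segments
#'
#' Normalized hydraulic resistance \eqn{R_t/R_{HP}} of a curved vessel,
#' \deqn{R_t/R_{HP} = 0.526 + \sqrt{0.225 + 0.022\,\sqrt{d/a_k}\,Re},}
#' a semi-empirical law for the extra dissipation by the secondary flows in
#' bends. At Re = 0 (or for a very large curvature radius) it reduces to
#' \eqn{0.526+\sqrt{0.225} \approx 1.0003}, i.e. the Hagen-Poiseuille
#' limit, and it is monotone non-decreasing in both Re and \eqn{d/a_k}.
#'
#' The Reynolds number argument is taken exactly as supplied; which
#' convention (diameter- or radius-based) the correction is calibrated
#' against is chosen one level up, in [segment_resistance()].
#'
#' @param re Reynolds number (\eqn{\ge 0}, vectorized).
#' @param geom a [segment_geometry()].
#' @return dimensionless resistance ratio \eqn{\ge 1.0003}.
#' @examples
#' ica <- segment_geometry(250, 4, 10, "tortuous")
#' tortuous_ratio(0, ica)       # Hagen-Poiseuille limit
#' tortuous_ratio(434.5, ica)   # ~3.030
#' @export
tortuous_ratio <- function(re, geom) {
  stopifnot(inherits(geom, "cow_geometry"), is.numeric(re))
  if (any(re < 0)) stop("Reynolds number must be >= 0", call. = FALSE)
  .ratio_tortuous(re, geom$diameter, geom$curvature_radius)
}

#' Resistance correction for short (entrance-dominated) segments
#'
#' Normalized hydraulic resistance \eqn{R_l/R_{HP}} of a short vessel in
#' which the velocity profile is still developing,
#' \deqn{R_l/R_{HP} = 1 + 0.044\,(d/l)\,Re.}
#' Exactly 1 at Re = 0 and linear in Re.
#'
#' @inheritParams tortuous_ratio
#' @return dimensionless resistance ratio \eqn{\ge 1}.
#' @examples
#' acoa <- segment_geometry(5, 1.2, 40, "entrance")
#' entrance_ratio(100, acoa)   # 2.056
#' @export
entrance_ratio <- function(re, geom) {
  stopifnot(inherits(geom, "cow_geometry"), is.numeric(re))
  if (any(re < 0)) stop("Reynolds number must be >= 0", call. = FALSE)
  .ratio_entrance(re, geom$diameter, geom$length)
}

#' Flow-dependent resistance of one segment
#'
#' In `"linear"` mode this is the Hagen-Poiseuille resistance regardless of
#' flow. In `"nonlinear"` mode the Hagen-Poiseuille value is multiplied by
#' the correction assigned to the segment ([tortuous_ratio()] or
#' [entrance_ratio()]), evaluated at the segment's Reynolds number.
#'
#' The semi-empirical corrections are calibrated against a radius-based
#' Reynolds number (\eqn{\rho \bar v r/\mu}, half the diameter-based value
#' reported by [reynolds_number()]); `re_convention = "radius"` is
#' therefore the default and is what reproduces the CFD benchmark flows
#' (see [validate_model()]). `"diameter"` feeds the diameter-based value
#' straight into the correction formulas.
#'
#' @param geom a [segment_geometry()].
#' @param flow volumetric flow, m\eqn{^3}/s (sign is ignored).
#' @param fluid a [fluid_properties()].
#' @param mode `"nonlinear"` or `"linear"`.
#' @param re_convention `"radius"` (default) or `"diameter"`: the Reynolds
#'   number convention fed to the correction formulas.
#' @return resistance in Pa·s/m\eqn{^3}.
#' @examples
#' ica <- segment_geometry(250, 4, 10, "tortuous")
#' segment_resistance(ica, 4.55e-6, mode = "linear")
#' segment_resistance(ica, 4.55e-6, mode = "nonlinear")
#' @export
segment_resistance <- function(geom, flow, fluid = fluid_properties(),
                               mode = c("nonlinear", "linear"),
                               re_convention = c("radius", "diameter")) {
  mode <- match.arg(tolower(mode), c("nonlinear", "linear"))
  re_convention <- match.arg(re_convention)
  r_hp <- hagen_poiseuille_resistance(geom, fluid)
  if (mode == "linear") return(r_hp)
  re <- reynolds_number(flow, geom, fluid)
  if (re_convention == "radius") re <- re / 2
  ratio <- switch(geom$formula,
    tortuous = .ratio_tortuous(re, geom$diameter, geom$curvature_radius),
    entrance = .ratio_entrance(re, geom$diameter, geom$length),
    stop("unknown formula tag: ", geom$formula, call. = FALSE))
  r_hp * ratio
}
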
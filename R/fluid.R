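#' Blood properties for the lumped-parameter model
#'
#' The network model treats blood as a Newtonian fluid with a constant
#' dynamic viscosity; in the calibre of arteries forming the Circle of
#' Willis the shear-thinning of blood has a negligible effect on pressure
#' drops. The default viscosity is the high-shear (asymptotic) blood
#' viscosity 0.0035 Pa·s, the plateau every shear-thinning law converges to
#' at arterial shear rates, and the default density is 1050 kg/m\eqn{^3}.
#' A Carreau–Yasuda parameter set may be attached for rheological
#' side-calculations (see [carreau_yasuda_viscosity()]); it does not enter
#' the network solve.
#'
#' @param density blood density, kg/m\eqn{^3} (> 0).
#' @param viscosity constant dynamic viscosity, Pa·s (> 0).
#' @param cy_params optional list with elements `eta_0`, `eta_inf`
#'   (Pa·s), `lambda` (s), `a`, `n` (dimensionless); see
#'   [default_cy_params()].
#' @return An object of class `cow_fluid`.
#' @examples
#' fluid_properties()
#' fluid_properties(viscosity = 0.004)
#' @seealso [carreau_yasuda_viscosity()]
#' @export
fluid_properties <- function(density = 1050, viscosity = 0.0035,
                             cy_params = NULL) {
  stopifnot(is.numeric(density), length(density) == 1, is.finite(density),
            is.numeric(viscosity), length(viscosity) == 1, is.finite(viscosity))
  if (density <= 0) stop("blood density must be positive", call. = FALSE)
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (!is.null(cy_params)) cy_params <- .check_cy(cy_params)
  structure(list(density = density, viscosity = viscosity,
                 cy_params = cy_params),
            class = "cow_fluid")
}

.check_cy <- function(cy) {
  need <- c("eta_0", "eta_inf", "lambda", "a", "n")
  if (!is.list(cy) || !all(need %in% names(cy)))
    stop("cy_params must be a list with fields ",
         paste(need, collapse = ", "), call. = FALSE)
  cy <- cy[need]
  vals <- unlist(cy)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (!(cy$eta_0 > cy$eta_inf && cy$eta_inf > 0))
    stop("cy_params requires eta_0 > eta_inf > 0", call. = FALSE)
  if (cy$lambda <= 0 || cy$a <= 0)
    stop("cy_params requires lambda > 0 and a > 0", call. = FALSE)
  cy
}

#' Default Carreau-Yasuda parameters for blood
#'
#' Zero-shear viscosity 0.16 Pa·s, infinite-shear viscosity 0.0035 Pa·s,
#' relaxation time 8.2 s, transition exponent a = 0.64 and power index
#' n = 0.2128 — a standard parameterization of human blood.
#'
#' @return A list suitable for the `cy_params` field of
#'   [fluid_properties()].
#' @export
default_cy_params <- function() {
  list(eta_0 = 0.16, eta_inf = 0.0035, lambda = 8.2, a = 0.64, n = 0.2128)
}

#' Carreau-Yasuda shear-thinning viscosity
#'
#' Apparent dynamic viscosity of blood at a given shear strain rate under
#' the Carreau-Yasuda law
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
#'   \left(1+(\lambda\dot\gamma)^a\right)^{(n-1)/a}.}
#' The result is bounded by \eqn{[\eta_\infty, \eta_0]} and is monotone
#' non-increasing in the shear rate.
#'
#' @param shear_rate shear strain rate, 1/s (vectorized, must be \eqn{\ge 0}).
#' @param cy Carreau-Yasuda parameter list, default [default_cy_params()].
#' @return viscosity in Pa·s, same length as `shear_rate`.
#' @examples
#' carreau_yasuda_viscosity(0)      # eta_0
#' carreau_yasuda_viscosity(10)     # ~0.00804 Pa.s
#' @export
carreau_yasuda_viscosity <- function(shear_rate, cy = default_cy_params()) {
  if (is.null(cy)) stop("Carreau-Yasuda parameters are missing", call. = FALSE)
  cy <- .check_cy(cy)
  stopifnot(is.numeric(shear_rate))
  if (any(shear_rate < 0)) stop("shear_rate must be >= 0", call. = FALSE)
  cy$eta_inf + (cy$eta_0 - cy$eta_inf) *
    (1 + (cy$lambda * shear_rate)^cy$a)^((cy$n - 1) / cy$a)
}
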
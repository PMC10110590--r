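#' Physical constants and unit conversions
#'
#' The solver assembles everything in SI (Pa, m\eqn{^3}/s, Pa·s/m\eqn{^3});
#' the clinical dialect (mmHg, ml/min, mmHg·min/ml) is used at the interface.
#' `cow_constants()` returns the conversion factors in one place.
#'
#' @return A named list: `mmHg_Pa` (pascals per mmHg), `mlmin_m3s`
#'   (m\eqn{^3}/s per ml/min) and `R_SI_clinical` (Pa·s/m\eqn{^3} per
#'   mmHg·min/ml).
#' @examples
#' cow_constants()$mmHg_Pa
#' @export
cow_constants <- function() {
  list(
    mmHg_Pa = 133.322,
    mlmin_m3s = 1e-6 / 60,
    R_SI_clinical = 133.322 * 60 / 1e-6
  )
}

.mmHg <- 133.322
.mlmin <- 1e-6 / 60
.R_clin <- .mmHg / .mlmin   # Pa.s/m3 per mmHg.min/ml

#' Convert a hydraulic resistance between unit systems
#'
#' Reconciles resistances quoted in SI (`"Pa.s/m3"`) with the clinical
#' dialect (`"mmHg.min/ml"`). The conversion is the exact factor
#' \eqn{10^{-6}/(133.322 \times 60)} from SI to clinical units, so a round
#' trip is the identity to machine precision.
#'
#' @param value numeric vector of resistances.
#' @param from,to unit tags, one of `"Pa.s/m3"`, `"mmHg.min/ml"`.
#' @return numeric vector in the target units.
#' @examples
#' convert_resistance(4.22e9, "Pa.s/m3", "mmHg.min/ml")  # 0.52755
#' @export
convert_resistance <- function(value, from, to) {
  units <- c("Pa.s/m3", "mmHg.min/ml")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  stopifnot(is.numeric(value))
  if (from == to) return(value)
  if (from == "Pa.s/m3") value / .R_clin else value * .R_clin
}
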
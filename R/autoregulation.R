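#' Autoregulation parameters per territory
#'
#' Cerebral autoregulation keeps territory perfusion constant over a range
#' of perfusion pressures by dilating or constricting the downstream
#' arteriolar bed. The ideal characteristic used here gives each terminal
#' bed the resistance that would deliver exactly its target flow at the
#' current perfusion pressure, clipped to the physiological dilation/
#' constriction bounds:
#' \deqn{R_{bed} = \mathrm{clip}\left((P_{attach}-P_{drain})/q_{target},\;
#'   r_{min},\; r_{max}\right).}
#' Within the clip the bed flow equals the target; at the bounds the bed
#' behaves as a fixed resistance and flow follows pressure.
#'
#' @param territories data.frame with columns `territory`, `q_target`
#'   (ml/min), `r_min`, `r_max` (mmHg·min/ml), `p_lower`, `p_upper`
#'   (mmHg) and `drain` (mmHg).
#' @return An object of class `cow_autoreg_params`.
#' @seealso [default_autoregulation_params()]
#' @export
autoregulation_params <- function(territories) {
  need <- c("territory", "q_target", "r_min", "r_max",
            "p_lower", "p_upper", "drain")
  stopifnot(is.data.frame(territories))
  if (!all(need %in% names(territories)))
    stop("territories must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  t <- territories[need]
  if (any(t$q_target <= 0)) stop("q_target must be positive", call. = FALSE)
  if (any(t$r_min <= 0 | t$r_min >= t$r_max))
    stop("require 0 < r_min < r_max", call. = FALSE)
  if (any(t$p_lower >= t$p_upper))
    stop("require p_lower < p_upper", call. = FALSE)
  structure(t, class = c("cow_autoreg_params", "data.frame"))
}

#' Default autoregulation parameters
#'
#' Per side: anterior territory target 111 ml/min with bed resistance
#' bounds 0.46–1.31 mmHg·min/ml, middle 162 ml/min with 0.32–0.90, and
#' posterior 120 ml/min with 0.44–1.20; lower and upper autoregulation
#' limits 50 and 150 mmHg for every territory. Note the near identity
#' \eqn{r_{min} \approx p_{lower}/q_{target}} (e.g. 50/162 = 0.309 vs
#' 0.32): the resistance bounds are the ideal characteristic evaluated at
#' the pressure limits. Autoregulated beds drain to 0 mmHg by default,
#' the reference the bounds are quoted against.
#'
#' @return A `cow_autoreg_params` with six rows (three territories per
#'   side).
#' @examples
#' default_autoregulation_params()
#' @export
default_autoregulation_params <- function() {
  autoregulation_params(data.frame(
    territory = c("middle_L", "middle_R", "anterior_L", "anterior_R",
                  "posterior_L", "posterior_R"),
    q_target = c(162, 162, 111, 111, 120, 120),
    r_min = c(0.32, 0.32, 0.46, 0.46, 0.44, 0.44),
    r_max = c(0.90, 0.90, 1.31, 1.31, 1.20, 1.20),
    p_lower = 50, p_upper = 150, drain = 0,
    stringsAsFactors = FALSE))
}

# lumped cerebral-artery pressure per territory: mean of the probe
# segment's end-node pressures, falling back to the attach node where no
# probe artery is defined
.cerebral_pressure <- function(net, pressures, beds) {
  vapply(seq_len(nrow(beds)), function(j) {
    art <- beds$artery[j]
    if (is.na(art)) return(pressures[[beds$attach[j]]])
    i <- match(art, net$segments$name)
    (pressures[[net$segments$from[i]]] + pressures[[net$segments$to[i]]]) / 2
  }, numeric(1))
}

#' Solve a network under ideal autoregulation
#'
#' Replaces the network's terminal beds by the ideal autoregulation
#' controller and solves for the joint fixed point: bed resistances follow
#' the clipped ideal characteristic of the attach-node pressure while the
#' segment resistances follow the flow-dependent formulas. The two
#' updates are interleaved in a single under-relaxed loop with a shared
#' convergence test (avoiding nested-loop stalls).
#'
#' Each territory is classified from the unclipped required resistance
#' \eqn{(P_{attach}-P_{drain})/q_{target}}: `WITHIN` when it lies in
#' \eqn{[r_{min}, r_{max}]} (bed flow equals the target), `BELOW_LOWER`
#' when it falls below \eqn{r_{min}} (maximal dilation, flow sags) and
#' `ABOVE_UPPER` above \eqn{r_{max}}.
#'
#' @param net a `cow_network`; its bed resistances/drains are ignored in
#'   favour of the controller, but attach nodes, probe arteries and
#'   territory names are taken from it. Territory names must match
#'   `params`.
#' @param params a [autoregulation_params()].
#' @param settings a [solver_settings()]; `mode = "linear"` gives the
#'   linear-resistance comparison model with the same controller.
#' @return An object of class `cow_regulated`: `solution` (the underlying
#'   `cow_solution`), `bed_resistances`, `required_resistance`,
#'   `regulation_state`, `perfusion_pressure` (attach node, mmHg),
#'   `cerebral_pressure` (lumped cerebral-artery probe, mmHg) and `apr`
#'   (the [compute_apr()] table).
#' @examples
#' reg <- regulate(reference_network())
#' reg$solution$bed_flows[["middle_L"]]   # 162, within regulation
#' @export
regulate <- function(net, params = default_autoregulation_params(),
                     settings = solver_settings()) {
  stopifnot(inherits(net, "cow_network"),
            inherits(params, "cow_autoreg_params"),
            inherits(settings, "cow_solver_settings"))
  j <- match(net$beds$territory, params$territory)
  if (anyNA(j))
    stop("no autoregulation parameters for territory: ",
         paste(net$beds$territory[is.na(j)], collapse = ", "), call. = FALSE)
  par <- params[j, ]
  net$beds$drain <- par$drain
  q_si <- par$q_target * .mlmin
  rmin_si <- par$r_min * (.mmHg / .mlmin)
  rmax_si <- par$r_max * (.mmHg / .mlmin)
  drain_si <- par$drain * .mmHg
  attach <- net$beds$attach
  ctrl <- function(p, R_bed) {
    pmin(pmax((p[attach] - drain_si) / q_si, rmin_si), rmax_si)
  }
  sol <- .solve_core(net, settings, bed_ctrl = ctrl,
                     R_bed0 = (rmin_si + rmax_si) / 2)
  p_attach <- sol$node_pressures[attach]
  required <- (p_attach - par$drain) / par$q_target
  state <- ifelse(required < par$r_min, "BELOW_LOWER",
                  ifelse(required > par$r_max, "ABOVE_UPPER", "WITHIN"))
  p_cer <- .cerebral_pressure(net, sol$node_pressures, net$beds)
  out <- structure(list(
    solution = sol,
    bed_resistances = stats::setNames(unname(sol$bed_resistances),
                                      net$beds$territory),
    required_resistance = stats::setNames(unname(required),
                                          net$beds$territory),
    regulation_state = stats::setNames(unname(state), net$beds$territory),
    perfusion_pressure = stats::setNames(unname(p_attach),
                                         net$beds$territory),
    cerebral_pressure = stats::setNames(p_cer, net$beds$territory),
    params = params),
    class = "cow_regulated")
  out$apr <- compute_apr(out, params)
  out
}

#' @export
print.cow_regulated <- function(x, ...) {
  cat(sprintf("<cow_regulated> %s mode, %d iterations\n",
              x$solution$mode, x$solution$iterations))
  print(x$apr, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Autoregulation pressure reserve (APR)
#'
#' The APR is the pair of signed margins between the pressure at the level
#' of the major cerebral arteries and the autoregulation limits:
#' \deqn{APR = \{\,P^* - P_{lower},\; P_{upper} - P^*\,\},}
#' where \eqn{P^*} is the territory's lumped cerebral-artery pressure
#' (`cerebral_pressure` of the regulated solution). When both components
#' are positive the territory's flow is preserved; a negative lower
#' (upper) reserve signals exit from autoregulation by too low (too high)
#' pressure.
#'
#' @param sol a `cow_regulated` from [regulate()].
#' @param params a [autoregulation_params()].
#' @return data.frame with one row per territory: `territory`, `pressure`
#'   (the probe pressure \eqn{P^*}, mmHg), `flow` (bed flow, ml/min),
#'   `state` and `apr_lower`, `apr_upper` (mmHg).
#' @examples
#' reg <- regulate(reference_network())
#' compute_apr(reg, default_autoregulation_params())
#' @export
compute_apr <- function(sol, params = default_autoregulation_params()) {
  stopifnot(inherits(sol, "cow_regulated"),
            inherits(params, "cow_autoreg_params"))
  terr <- names(sol$cerebral_pressure)
  j <- match(terr, params$territory)
  if (anyNA(j)) stop("territory missing from params", call. = FALSE)
  p <- unname(sol$cerebral_pressure)
  data.frame(territory = terr,
             pressure = p,
             flow = unname(sol$solution$bed_flows[terr]),
             state = unname(sol$regulation_state[terr]),
             apr_lower = p - params$p_lower[j],
             apr_upper = params$p_upper[j] - p,
             stringsAsFactors = FALSE)
}

#' Critical stenosis severity for exit from autoregulation
#'
#' Sweeps the severity of a stenosis applied to the named segment(s)
#' (simultaneously, for bilateral sweeps) and returns the smallest
#' severity at which the named territory leaves the autoregulation range,
#' located by a coarse scan followed by bisection to `resolution`.
#'
#' With the default `criterion = "pressure"` the territory has exited when
#' either APR component turns negative, i.e. when its cerebral-artery
#' pressure crosses the `p_lower`/`p_upper` limits — the definition of the
#' reserve itself. `criterion = "saturation"` instead detects the bed's
#' regulation state leaving `WITHIN` (resistance clipped at a bound); the
#' two nearly coincide because \eqn{r_{min} \approx p_{lower}/q_{target}},
#' differing only by the rounding of the resistance bounds and by the
#' pressure drop along the cerebral-artery segment.
#'
#' @param net a `cow_network` (with any diameter overrides already
#'   applied).
#' @param params a [autoregulation_params()].
#' @param stenosed_segment segment name(s) swept; all receive the same
#'   severity at each sweep point.
#' @param territory the territory watched for exit.
#' @param resolution bisection half-width at which to stop (severity
#'   units).
#' @param settings a [solver_settings()].
#' @param criterion `"pressure"` (APR-based, default) or `"saturation"`.
#' @param coarse_step initial scan step over \eqn{[0, 1]}.
#' @return The exit severity (fraction of diameter lost), or `NA` — the
#'   no-exit sentinel — if the territory stays regulated through complete
#'   occlusion. The attribute `criterion` records the detection rule.
#' @examples
#' \donttest{
#' net <- set_diameter(reference_network(), "ACoA", 0.4)
#' find_autoregulation_exit(net, stenosed_segment = "ICAL",
#'                          territory = "middle_L")
#' }
#' @export
find_autoregulation_exit <- function(net,
                                     params = default_autoregulation_params(),
                                     stenosed_segment, territory,
                                     resolution = 1e-3,
                                     settings = solver_settings(),
                                     criterion = c("pressure", "saturation"),
                                     coarse_step = 0.05) {
  stopifnot(inherits(net, "cow_network"), resolution > 0,
            coarse_step > 0, coarse_step <= 1)
  criterion <- match.arg(criterion)
  .find_segment(net, stenosed_segment)
  if (!territory %in% net$beds$territory)
    stop("unknown territory: ", territory, call. = FALSE)
  within_at <- function(sev) {
    edited <- apply_stenosis(net, stenosed_segment, sev)
    reg <- regulate(edited, params, settings)
    if (criterion == "pressure") {
      a <- reg$apr[reg$apr$territory == territory, ]
      a$apr_lower > 0 && a$apr_upper > 0
    } else {
      reg$regulation_state[[territory]] == "WITHIN"
    }
  }
  lo <- 0; hi <- NA_real_
  for (sev in seq(0, 1, by = coarse_step)) {
    if (!within_at(sev)) { hi <- sev; break }
    lo <- sev
  }
  if (is.na(hi) && lo < 1 && !within_at(1)) { lo <- max(lo, 1 - coarse_step); hi <- 1 }
  if (is.na(hi)) return(structure(NA_real_, criterion = criterion))
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (within_at(mid)) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, criterion = criterion)
}
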
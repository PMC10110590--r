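#' Solver settings
#'
#' The nonlinear circuit is solved by fixed-point iteration: a nodal solve
#' with frozen resistances, then a resistance update from the formulas at
#' the freshly computed Reynolds numbers, under-relaxed to damp
#' oscillation at high Re, until the flows stop changing. The system is
#' tiny (about 14 unknown pressures), so a tight tolerance costs nothing.
#'
#' @param mode `"nonlinear"` (flow-dependent resistances) or `"linear"`
#'   (pure Hagen-Poiseuille, one exact solve).
#' @param rel_tolerance relative change in segment flows between
#'   successive iterates below which the iteration is declared converged.
#' @param max_iterations iteration cap; exceeding it raises a structured
#'   error of class `cow_convergence_error` carrying the last iterate.
#' @param relaxation under-relaxation factor in (0, 1] applied to
#'   resistance updates.
#' @param re_convention Reynolds-number convention fed to the correction
#'   formulas; see [segment_resistance()].
#' @return An object of class `cow_solver_settings`.
#' @export
solver_settings <- function(mode = c("nonlinear", "linear"),
                            rel_tolerance = 1e-8,
                            max_iterations = 200L,
                            relaxation = 0.5,
                            re_convention = c("radius", "diameter")) {
  mode <- match.arg(tolower(mode), c("nonlinear", "linear"))
  re_convention <- match.arg(re_convention)
  stopifnot(rel_tolerance > 0, max_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(mode = mode, rel_tolerance = rel_tolerance,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation, re_convention = re_convention),
            class = "cow_solver_settings")
}

# Precompute assembly indices; raises cow_singular_error when an unknown
# node has no path to a fixed-pressure boundary through patent elements.
.assemble <- function(net) {
  nodes <- net$nodes; segs <- net$segments; beds <- net$beds
  ids <- nodes$id
  fixed <- nodes$kind %in% c("INLET", "REFERENCE") & is.finite(nodes$pressure)
  p_fixed <- nodes$pressure * .mmHg
  unk <- ids[!fixed]
  pat <- which(segs$patent)

  # reachability from fixed nodes through patent segments and beds
  reach <- stats::setNames(fixed, ids)
  edges_a <- c(segs$from[pat], beds$attach)
  edges_b <- c(segs$to[pat], rep("<drain>", nrow(beds)))
  reach <- c(reach, "<drain>" = TRUE)
  repeat {
    r2 <- reach
    hit <- reach[edges_a] | reach[edges_b]
    r2[edges_a] <- r2[edges_a] | hit
    r2[edges_b] <- r2[edges_b] | hit
    if (identical(r2, reach)) break
    reach <- r2
  }
  dead <- unk[!reach[unk]]
  if (length(dead)) {
    cond <- structure(
      class = c("cow_singular_error", "error", "condition"),
      list(message = paste0("nodes disconnected from every pressure ",
                            "boundary: ", paste(dead, collapse = ", ")),
           call = sys.call(-1), nodes = dead))
    stop(cond)
  }

  list(ids = ids, fixed = fixed, p_fixed = p_fixed, unk = unk,
       iu = stats::setNames(match(ids, unk), ids),
       from = segs$from, to = segs$to, patent = segs$patent,
       r_hp = .hp(segs$length, segs$diameter, net$fluid$viscosity),
       d = segs$diameter, ak = segs$curvature, len = segs$length,
       tort = segs$formula == "tortuous",
       attach = beds$attach, drain = beds$drain * .mmHg)
}

# One linear nodal solve at frozen resistances (SI units).
.nodal_solve <- function(asm, R_seg, R_bed) {
  n <- length(asm$unk)
  p_all <- stats::setNames(asm$p_fixed, asm$ids)
  if (n > 0) {
    G <- matrix(0, n, n)
    b <- numeric(n)
    for (i in which(asm$patent)) {
      g <- 1 / R_seg[i]
      a1 <- asm$iu[[asm$from[i]]]; a2 <- asm$iu[[asm$to[i]]]
      if (!is.na(a1)) {
        G[a1, a1] <- G[a1, a1] + g
        if (!is.na(a2)) G[a1, a2] <- G[a1, a2] - g
        else b[a1] <- b[a1] + g * p_all[[asm$to[i]]]
      }
      if (!is.na(a2)) {
        G[a2, a2] <- G[a2, a2] + g
        if (!is.na(a1)) G[a2, a1] <- G[a2, a1] - g
        else b[a2] <- b[a2] + g * p_all[[asm$from[i]]]
      }
    }
    for (j in seq_along(asm$attach)) {
      a <- asm$iu[[asm$attach[j]]]
      if (is.na(a)) next
      g <- 1 / R_bed[j]
      G[a, a] <- G[a, a] + g
      b[a] <- b[a] + g * asm$drain[j]
    }
    p_all[asm$unk] <- solve(G, b)
  }
  Q <- ifelse(asm$patent, (p_all[asm$from] - p_all[asm$to]) / R_seg, 0)
  Qbed <- (p_all[asm$attach] - asm$drain) / R_bed
  list(p = p_all, Q = unname(Q), Qbed = unname(Qbed))
}

# Shared fixed-point core. bed_ctrl, when given, is a function
# (p_all_SI, R_bed_SI) -> target bed resistances (SI); its convergence is
# folded into the same loop as the segment-resistance update.
.solve_core <- function(net, settings, bed_ctrl = NULL, R_bed0 = NULL,
                        init = NULL) {
  asm <- .assemble(net)
  rho <- net$fluid$density; mu <- net$fluid$viscosity
  re_k <- if (settings$re_convention == "radius") 0.5 else 1
  R <- if (is.null(init)) asm$r_hp else init
  R_bed <- if (is.null(R_bed0)) net$beds$resistance * (.mmHg / .mlmin) else R_bed0
  nonlin <- settings$mode == "nonlinear"
  w <- settings$relaxation
  Qold <- NULL
  converged <- FALSE
  for (it in seq_len(settings$max_iterations)) {
    s <- .nodal_solve(asm, R, R_bed)
    re <- .re_diam(s$Q, asm$d, rho, mu)
    if (nonlin) {
      ratio <- ifelse(asm$tort,
                      .ratio_tortuous(re_k * re, asm$d, asm$ak),
                      .ratio_entrance(re_k * re, asm$d, asm$len))
      Rtar <- asm$r_hp * ratio
    } else Rtar <- asm$r_hp
    dbed <- 0
    if (!is.null(bed_ctrl) && length(R_bed)) {
      Rbtar <- bed_ctrl(s$p, R_bed)
      dbed <- max(abs(Rbtar - R_bed) / Rbtar)
      R_bed <- R_bed + w * (Rbtar - R_bed)
    }
    if (!is.null(Qold)) {
      # absolute floor (1e-15 m3/s ~ 6e-8 ml/min) keeps rounding noise in
      # zero-flow configurations from stalling the relative test
      scale <- if (length(s$Q)) max(abs(s$Q), abs(Qold)) else 0
      dq_abs <- if (length(s$Q)) max(abs(s$Q - Qold)) else 0
      if (dq_abs <= max(settings$rel_tolerance * scale, 1e-15) &&
          dbed <= settings$rel_tolerance) {
        converged <- TRUE
        break
      }
    } else if (!nonlin && is.null(bed_ctrl)) {
      converged <- TRUE
      break
    }
    Qold <- s$Q
    R <- R + w * (Rtar - R)
  }
  sol <- structure(list(
    node_pressures = s$p / .mmHg,
    segment_flows = stats::setNames(s$Q / .mlmin, net$segments$name),
    segment_re = stats::setNames(re, net$segments$name),
    segment_resistances = stats::setNames(
      ifelse(asm$patent, R / (.mmHg / .mlmin), NA_real_),
      net$segments$name),
    segment_dp = stats::setNames(
      ifelse(asm$patent,
             (s$p[net$segments$from] - s$p[net$segments$to]) / .mmHg,
             NA_real_),
      net$segments$name),
    bed_flows = stats::setNames(s$Qbed / .mlmin, net$beds$territory),
    bed_resistances = stats::setNames(R_bed / (.mmHg / .mlmin),
                                      net$beds$territory),
    iterations = it, converged = converged, mode = settings$mode),
    class = "cow_solution")
  if (!converged) {
    cond <- structure(
      class = c("cow_convergence_error", "error", "condition"),
      list(message = sprintf(
        "fixed-point iteration did not converge in %d iterations",
        settings$max_iterations),
        call = sys.call(-1), last_solution = sol))
    stop(cond)
  }
  sol
}

#' Solve the network with linear (Hagen-Poiseuille) resistances
#'
#' One exact conductance-matrix solve of the nodal equations: flow balance
#' at every non-fixed node with node pressures as unknowns, terminal beds
#' entering as ordinary conductances toward their drain pressures. The
#' linear mode is the comparison baseline for quantifying what the
#' hydrodynamic nonlinearities contribute; it systematically overestimates
#' cerebral flows.
#'
#' @param net a `cow_network`.
#' @return A `cow_solution`: node pressures (mmHg), signed segment flows
#'   (ml/min, positive from `from` to `to`), Reynolds numbers, converged
#'   segment resistances (mmHg·min/ml), per-segment pressure drops (mmHg)
#'   and terminal-bed flows (ml/min).
#' @examples
#' sol <- solve_linear(reference_network())
#' sol$segment_flows[["M1L"]]
#' @export
solve_linear <- function(net) {
  stopifnot(inherits(net, "cow_network"))
  .solve_core(net, solver_settings(mode = "linear"))
}

#' Solve the network with flow-dependent resistances
#'
#' Fixed point of the loop (resistances from the correction formulas at
#' the current Reynolds numbers) then (nodal solve at those
#' resistances), initialized at the Hagen-Poiseuille solution unless
#' `init` is given. Convergence is declared when the relative change in
#' every segment flow falls below `settings$rel_tolerance`; the solution
#' is independent of initialization to within that tolerance.
#'
#' @param net a `cow_network`.
#' @param settings a [solver_settings()].
#' @param init optional initial segment resistances in Pa·s/m\eqn{^3}
#'   (one per segment) to start the iteration from.
#' @return A `cow_solution`; see [solve_linear()].
#' @examples
#' sol <- solve_nonlinear(reference_network())
#' sol$segment_flows[["M1L"]]
#' @export
solve_nonlinear <- function(net, settings = solver_settings(), init = NULL) {
  stopifnot(inherits(net, "cow_network"),
            inherits(settings, "cow_solver_settings"))
  settings$mode <- "nonlinear"
  .solve_core(net, settings, init = init)
}

#' Flow-conservation audit of a solution
#'
#' Signed sum of flows at every non-fixed node (segment inflow minus
#' outflow minus terminal-bed outflow), in ml/min. For any converged
#' solution the largest residual is at rounding level; the audit is mainly
#' useful for hand-edited states and regression tests.
#'
#' @param state a `cow_solution`.
#' @param net the `cow_network` it was solved on.
#' @return Named numeric vector of residuals (ml/min) with attribute
#'   `max_abs`.
#' @export
node_balance_residuals <- function(state, net) {
  stopifnot(inherits(state, "cow_solution"), inherits(net, "cow_network"))
  nodes <- net$nodes
  free <- nodes$id[!(nodes$kind %in% c("INLET", "REFERENCE") &
                       is.finite(nodes$pressure))]
  res <- stats::setNames(numeric(length(free)), free)
  Q <- state$segment_flows
  for (i in seq_len(nrow(net$segments))) {
    f <- net$segments$from[i]; t <- net$segments$to[i]
    q <- Q[[net$segments$name[i]]]
    if (f %in% free) res[f] <- res[f] - q
    if (t %in% free) res[t] <- res[t] + q
  }
  for (j in seq_len(nrow(net$beds))) {
    a <- net$beds$attach[j]
    if (a %in% free) res[a] <- res[a] - state$bed_flows[[net$beds$territory[j]]]
  }
  attr(res, "max_abs") <- max(abs(res))
  res
}

#' @export
print.cow_solution <- function(x, ...) {
  cat(sprintf("<cow_solution> %s mode, %d iteration%s, %sconverged\n",
              x$mode, x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "" else "NOT "))
  df <- as.data.frame(x)
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cow_solution <- function(x, ...) {
  data.frame(segment = names(x$segment_flows),
             flow_ml_min = unname(x$segment_flows),
             re = unname(x$segment_re),
             resistance_mmHg_min_ml = unname(x$segment_resistances),
             dp_mmHg = unname(x$segment_dp),
             stringsAsFactors = FALSE)
}
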
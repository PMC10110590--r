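#' Assemble a Circle of Willis network
#'
#' A network is a resistive circuit: nodes (pressure unknowns or fixed
#' boundary pressures), segments (tubes connecting nodes, each with a
#' geometry and a resistance formula) and terminal beds (lumped peripheral
#' resistances draining a perfusion territory to venous pressure).
#'
#' @param nodes data.frame with columns `id` (character), `kind` (one of
#'   `"INLET"`, `"INTERNAL"`, `"TERMINAL_OUTLET"`, `"REFERENCE"`) and
#'   `pressure` (mmHg; required for INLET/REFERENCE, `NA` otherwise).
#' @param segments data.frame with columns `name`, `from`, `to`
#'   (node ids), `length`, `diameter`, `curvature` (metres), `formula`
#'   (`"tortuous"`/`"entrance"`) and `patent` (logical).
#' @param beds data.frame with columns `territory`, `attach` (node id),
#'   `artery` (segment name whose lumped pressure stands for the
#'   territory's cerebral-artery pressure; may be `NA`), `resistance`
#'   (mmHg·min/ml, > 0) and `drain` (mmHg).
#' @param fluid a [fluid_properties()].
#' @return An object of class `cow_network`.
#' @seealso [reference_network()] for the bundled parameterization.
#' @export
cow_network <- function(nodes, segments, beds, fluid = fluid_properties()) {
  stopifnot(is.data.frame(nodes), is.data.frame(segments),
            is.data.frame(beds), inherits(fluid, "cow_fluid"))
  need_n <- c("id", "kind", "pressure")
  need_s <- c("name", "from", "to", "length", "diameter", "curvature",
              "formula", "patent")
  need_b <- c("territory", "attach", "artery", "resistance", "drain")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns ", paste(need_n, collapse = ", "), call. = FALSE)
  if (!all(need_s %in% names(segments)))
    stop("segments must have columns ", paste(need_s, collapse = ", "), call. = FALSE)
  if (!all(need_b %in% names(beds)))
    stop("beds must have columns ", paste(need_b, collapse = ", "), call. = FALSE)
  nodes <- nodes[need_n]; segments <- segments[need_s]; beds <- beds[need_b]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(segments$name)) stop("duplicate segment names", call. = FALSE)
  bad_kind <- setdiff(nodes$kind,
                      c("INLET", "INTERNAL", "TERMINAL_OUTLET", "REFERENCE"))
  if (length(bad_kind)) stop("unknown node kind: ", bad_kind[1], call. = FALSE)
  fixed <- nodes$kind %in% c("INLET", "REFERENCE")
  if (any(fixed & !is.finite(nodes$pressure)))
    stop("INLET and REFERENCE nodes must carry a fixed pressure", call. = FALSE)
  if (any(segments$length <= 0 | segments$diameter <= 0 |
          segments$curvature <= 0))
    stop("segment dimensions must be positive", call. = FALSE)
  if (any(beds$resistance <= 0))
    stop("terminal bed resistance must be positive", call. = FALSE)
  net <- structure(list(nodes = nodes, segments = segments, beds = beds,
                        fluid = fluid),
                   class = "cow_network")
  diag <- validate_topology(net)
  err <- diag$code == "structure"
  if (any(err)) stop("invalid network: ", diag$message[which(err)[1]],
                     call. = FALSE)
  net
}

#' The bundled reference Circle of Willis
#'
#' The 18-element circuit: both internal carotids (ICA) and both
#' vertebrals (VA) as 93 mmHg pressure inlets, the basilar artery (BA),
#' the proximal and distal cerebral segments (A1/A2, M1, P1/P2) and the
#' communicating anastomoses (ACoA, both PCoA). Long or markedly curved
#' vessels carry the tortuous-resistance formula; the short proximal and
#' communicating segments (A1, P1, PCoA, ACoA) carry the entrance formula.
#' Six terminal beds (anterior/middle/posterior, left/right) drain the
#' distal A2/M1/P2 ends through fixed peripheral resistances
#' (7.04/3.52/4.22 \eqn{\times 10^9} Pa·s/m\eqn{^3}) to a 10 mmHg venous
#' pressure — the fixed-resistance configuration used for validation
#' against the CFD benchmark. [regulate()] replaces these beds with the
#' autoregulation controller.
#'
#' Positive flow directions: supplying arteries point into the circle;
#' PCoA positive flow is anterior to posterior (ICA terminus toward the
#' posterior junction); ACoA positive flow is left to right.
#'
#' @param fluid a [fluid_properties()].
#' @return A `cow_network`.
#' @examples
#' net <- reference_network()
#' net
#' @export
reference_network <- function(fluid = fluid_properties()) {
  segs <- data.frame(
    name = c("ICAL", "ICAR", "VAL", "VAR", "BA",
             "P1L", "P1R", "PCoAL", "PCoAR", "P2L", "P2R",
             "M1L", "M1R", "A1L", "A1R", "ACoA", "A2L", "A2R"),
    from = c("in_ICAL", "in_ICAR", "in_VAL", "in_VAR", "BA_orig",
             "BA_top", "BA_top", "ICAterm_L", "ICAterm_R", "post_L", "post_R",
             "ICAterm_L", "ICAterm_R", "ICAterm_L", "ICAterm_R", "ant_L",
             "ant_L", "ant_R"),
    to = c("ICAterm_L", "ICAterm_R", "BA_orig", "BA_orig", "BA_top",
           "post_L", "post_R", "post_L", "post_R", "out_P2L", "out_P2R",
           "out_M1L", "out_M1R", "ant_L", "ant_R", "ant_R",
           "out_A2L", "out_A2R"),
    length = c(250, 250, 130, 130, 23,
               7.23, 7.23, 10.30, 10.30, 29.07, 29.07,
               30.78, 30.78, 13.17, 13.17, 5, 32.37, 32.37) * 1e-3,
    diameter = c(4, 4, 3.7, 3.7, 4,
                 1.9, 1.9, 0.87, 0.87, 1.9, 1.9,
                 2.7, 2.7, 2.2, 2.2, 1.2, 2.2, 2.2) * 1e-3,
    curvature = c(10, 10, 35, 35, 25,
                  5, 5, 5, 5, 12, 12,
                  12.5, 12.5, 5, 5, 40, 15, 15) * 1e-3,
    formula = c("tortuous", "tortuous", "tortuous", "tortuous", "tortuous",
                "entrance", "entrance", "entrance", "entrance",
                "tortuous", "tortuous", "tortuous", "tortuous",
                "entrance", "entrance", "entrance", "tortuous", "tortuous"),
    patent = TRUE,
    stringsAsFactors = FALSE)
  nodes <- data.frame(
    id = c("in_ICAL", "in_ICAR", "in_VAL", "in_VAR",
           "BA_orig", "BA_top", "ICAterm_L", "ICAterm_R",
           "post_L", "post_R", "ant_L", "ant_R",
           "out_M1L", "out_M1R", "out_A2L", "out_A2R", "out_P2L", "out_P2R"),
    kind = c(rep("INLET", 4), rep("INTERNAL", 8), rep("TERMINAL_OUTLET", 6)),
    pressure = c(rep(93, 4), rep(NA_real_, 14)),
    stringsAsFactors = FALSE)
  beds <- data.frame(
    territory = c("middle_L", "middle_R", "anterior_L", "anterior_R",
                  "posterior_L", "posterior_R"),
    attach = c("out_M1L", "out_M1R", "out_A2L", "out_A2R",
               "out_P2L", "out_P2R"),
    artery = c("M1L", "M1R", "A2L", "A2R", "P2L", "P2R"),
    resistance = convert_resistance(
      c(3.52e9, 3.52e9, 7.04e9, 7.04e9, 4.22e9, 4.22e9),
      "Pa.s/m3", "mmHg.min/ml"),
    drain = 10,
    stringsAsFactors = FALSE)
  cow_network(nodes, segs, beds, fluid)
}

#' @export
print.cow_network <- function(x, ...) {
  n_pat <- sum(x$segments$patent)
  cat(sprintf("<cow_network> %d nodes, %d segments (%d patent), %d terminal beds\n",
              nrow(x$nodes), nrow(x$segments), n_pat, nrow(x$beds)))
  inl <- x$nodes[x$nodes$kind == "INLET", ]
  cat("  inlets: ", paste(sprintf("%s = %g mmHg", inl$id, inl$pressure),
                          collapse = ", "), "\n", sep = "")
  if (n_pat < nrow(x$segments))
    cat("  occluded: ",
        paste(x$segments$name[!x$segments$patent], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

.find_segment <- function(net, segment_name) {
  i <- match(segment_name, net$segments$name)
  if (anyNA(i))
    stop("unknown segment: ",
         paste(segment_name[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Apply a stenosis to a named segment
#'
#' A stenosis of severity \eqn{s} (the fractional diameter change) scales
#' the whole segment's diameter by \eqn{1-s}; the lumped model carries no
#' sub-segment localization, so the narrowing is uniform along the vessel
#' and the resistance follows from the formulas at the reduced diameter.
#' Severity 1 marks the segment non-patent (complete occlusion).
#'
#' @param net a `cow_network`.
#' @param segment_name name(s) of segment(s) to narrow.
#' @param severity diameter-reduction fraction in \eqn{[0, 1]} (scalar,
#'   applied to every named segment).
#' @return An edited copy of the network.
#' @examples
#' net <- apply_stenosis(reference_network(), "ICAL", 0.341)
#' @export
apply_stenosis <- function(net, segment_name, severity) {
  stopifnot(inherits(net, "cow_network"), is.numeric(severity),
            length(severity) == 1)
  if (severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]", call. = FALSE)
  i <- .find_segment(net, segment_name)
  if (severity >= 1) {
    net$segments$patent[i] <- FALSE
  } else {
    net$segments$diameter[i] <- net$segments$diameter[i] * (1 - severity)
  }
  net
}

#' Override a segment diameter
#'
#' Used for anatomical-variant studies, e.g. setting the ACoA to 0.4 mm
#' (hypoplastic) or 1.6 mm (generous collateral).
#'
#' @param net a `cow_network`.
#' @param segment_name name(s) of segment(s) to edit.
#' @param diameter new internal diameter in mm (> 0; recycled).
#' @return An edited copy of the network.
#' @examples
#' net <- set_diameter(reference_network(), "ACoA", 0.4)
#' @export
set_diameter <- function(net, segment_name, diameter) {
  stopifnot(inherits(net, "cow_network"), is.numeric(diameter))
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  i <- .find_segment(net, segment_name)
  net$segments$diameter[i] <- rep_len(diameter, length(i)) * 1e-3
  net
}

#' Occlude (remove) segments from the circuit
#'
#' Marks the named segments non-patent; they are excluded from circuit
#' assembly entirely (rather than being given a huge resistance), which
#' keeps the conductance matrix well conditioned.
#'
#' @param net a `cow_network`.
#' @param segment_name name(s) of segment(s) to occlude.
#' @return An edited copy of the network.
#' @export
occlude <- function(net, segment_name) {
  stopifnot(inherits(net, "cow_network"))
  i <- .find_segment(net, segment_name)
  net$segments$patent[i] <- FALSE
  net
}

#' Set the inlet pressures of a network
#'
#' @param net a `cow_network`.
#' @param pressure pressure in mmHg, recycled over all INLET nodes (or a
#'   named vector of node ids).
#' @return An edited copy of the network.
#' @export
set_inlet_pressure <- function(net, pressure) {
  stopifnot(inherits(net, "cow_network"), is.numeric(pressure))
  i <- which(net$nodes$kind == "INLET")
  if (!is.null(names(pressure))) {
    j <- match(names(pressure), net$nodes$id)
    if (anyNA(j)) stop("unknown inlet node", call. = FALSE)
    net$nodes$pressure[j] <- pressure
  } else {
    net$nodes$pressure[i] <- rep_len(pressure, length(i))
  }
  net
}

#' Diagnose the structure of a network
#'
#' Structural audit run before every solve: segment endpoints and bed
#' attach nodes must exist (`code = "structure"`), every terminal bed
#' should be reachable from some inlet through patent segments
#' (`code = "unsupplied"`), every inlet should feed something
#' (`code = "dangling"`), and internal nodes should not be isolated.
#' Diagnostics are returned, not raised; the reference network returns an
#' empty table.
#'
#' @param net a `cow_network`.
#' @return data.frame with columns `code` and `message`; zero rows when no
#'   problems are found.
#' @export
validate_topology <- function(net) {
  stopifnot(is.list(net))
  out <- data.frame(code = character(), message = character(),
                    stringsAsFactors = FALSE)
  add <- function(code, message)
    rbind(out, data.frame(code = code, message = message,
                          stringsAsFactors = FALSE))
  ids <- net$nodes$id
  ep <- unique(c(net$segments$from, net$segments$to))
  missing_ep <- setdiff(ep, ids)
  if (length(missing_ep))
    out <- add("structure", paste0("segment endpoint not in node table: ",
                                   paste(missing_ep, collapse = ", ")))
  missing_at <- setdiff(net$beds$attach, ids)
  if (length(missing_at))
    out <- add("structure", paste0("bed attach node not in node table: ",
                                   paste(missing_at, collapse = ", ")))
  bad_art <- setdiff(stats::na.omit(net$beds$artery), net$segments$name)
  if (length(bad_art))
    out <- add("structure", paste0("bed artery not a segment: ",
                                   paste(bad_art, collapse = ", ")))
  if (nrow(out)) return(out)

  # connected components over patent segments
  comp <- stats::setNames(seq_along(ids), ids)
  pat <- net$segments[net$segments$patent, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pat))) {
      a <- pat$from[i]; b <- pat$to[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == max(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  inlet_comp <- unique(comp[ids[net$nodes$kind == "INLET"]])
  for (j in seq_len(nrow(net$beds))) {
    if (!(comp[net$beds$attach[j]] %in% inlet_comp))
      out <- add("unsupplied",
                 paste0("territory ", net$beds$territory[j],
                        " is not reachable from any inlet"))
  }
  deg <- table(factor(c(pat$from, pat$to), levels = ids))
  for (id in ids[net$nodes$kind == "INLET"]) {
    if (deg[[id]] == 0)
      out <- add("dangling", paste0("inlet ", id, " feeds no patent segment"))
  }
  for (id in ids[net$nodes$kind == "INTERNAL"]) {
    if (deg[[id]] == 0)
      out <- add("dangling", paste0("internal node ", id, " is isolated"))
  }
  out
}
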
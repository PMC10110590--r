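#' Define a simulation scenario
#'
#' A scenario bundles a base network, a list of anatomical edits, an
#' optional stenosis sweep and the solver configuration, mirroring the
#' occlusion/stenosis experiments the model is built for: single-vessel
#' occlusions, progressive unilateral or bilateral (simultaneous) ICA
#' stenosis, and communicating-artery diameter sensitivity studies.
#'
#' @param name scenario label (appears in the result table).
#' @param base `"reference"` (the bundled network), a path to a network
#'   file, or a `cow_network`.
#' @param edits list of edits applied in order; each edit is a list with
#'   `op` one of `"set_diameter"` (fields `segment`, `value` in mm),
#'   `"stenosis"` (`segment`, `severity`) or `"occlude"` (`segment`).
#' @param sweep optional list with `segments` (character), `severities`
#'   (strictly increasing grid in \eqn{[0, 1]}) and `simultaneous`
#'   (logical: apply the same severity to all named segments at once;
#'   otherwise each segment is swept separately).
#' @param mode `"nonlinear"` or `"linear"`.
#' @param regulation logical: solve under the autoregulation controller
#'   ([regulate()]) instead of the network's fixed terminal resistances.
#' @param params autoregulation parameters used when `regulation = TRUE`.
#' @return An object of class `cow_scenario`.
#' @seealso [run_scenario()], [read_scenario()]
#' @export
cow_scenario <- function(name, base = "reference", edits = list(),
                         sweep = NULL, mode = c("nonlinear", "linear"),
                         regulation = FALSE,
                         params = default_autoregulation_params()) {
  mode <- match.arg(tolower(mode), c("nonlinear", "linear"))
  stopifnot(is.character(name), length(name) == 1, is.list(edits),
            is.logical(regulation))
  for (e in edits) {
    if (!is.list(e) || is.null(e$op) ||
        !e$op %in% c("set_diameter", "stenosis", "occlude"))
      stop("each edit needs op in set_diameter/stenosis/occlude",
           call. = FALSE)
    if (is.null(e$segment)) stop("edit lacks a segment field", call. = FALSE)
  }
  if (!is.null(sweep)) {
    if (is.null(sweep$segments) || is.null(sweep$severities))
      stop("sweep needs fields segments and severities", call. = FALSE)
    sv <- sweep$severities
    if (any(sv < 0 | sv > 1) || is.unsorted(sv, strictly = TRUE))
      stop("sweep severities must be strictly increasing within [0, 1]",
           call. = FALSE)
    if (is.null(sweep$simultaneous)) sweep$simultaneous <- TRUE
  }
  structure(list(name = name, base = base, edits = edits, sweep = sweep,
                 mode = mode, regulation = regulation, params = params),
            class = "cow_scenario")
}

.scenario_base <- function(base) {
  if (inherits(base, "cow_network")) return(base)
  if (identical(base, "reference")) return(reference_network())
  read_cow_network(base)
}

.apply_edits <- function(net, edits) {
  for (e in edits) {
    net <- switch(e$op,
      set_diameter = set_diameter(net, e$segment, e$value),
      stenosis = apply_stenosis(net, e$segment, e$severity),
      occlude = occlude(net, e$segment))
  }
  net
}

.result_row <- function(scenario, sweep_segment, severity, record, name,
                        flow, re = NA_real_, resistance = NA_real_,
                        dp = NA_real_, attach_pressure = NA_real_,
                        cerebral_pressure = NA_real_, state = NA_character_,
                        apr_lower = NA_real_, apr_upper = NA_real_) {
  data.frame(scenario = scenario, sweep_segment = sweep_segment,
             severity = severity, record = record, name = name,
             flow_ml_min = flow, re = re,
             resistance_mmHg_min_ml = resistance, dp_mmHg = dp,
             attach_pressure_mmHg = attach_pressure,
             cerebral_pressure_mmHg = cerebral_pressure, state = state,
             apr_lower = apr_lower, apr_upper = apr_upper,
             stringsAsFactors = FALSE)
}

#' Run a scenario
#'
#' Executes the scenario's edits, then one solve per sweep point (or a
#' single solve when no sweep is defined), and returns one tidy table:
#' segment records carry flow, Reynolds number, resistance and pressure
#' drop; when regulation is on, territory records additionally carry bed
#' flow, attach and cerebral-artery pressures, regulation state and the
#' APR components. Output is deterministic for identical input.
#'
#' @param s a [cow_scenario()].
#' @param settings optional [solver_settings()]; the scenario's `mode`
#'   overrides the settings' mode.
#' @return data.frame; columns documented above, `NA` where a column does
#'   not apply to a record kind.
#' @examples
#' one <- cow_scenario("ICAL occlusion",
#'                     edits = list(list(op = "occlude", segment = "ICAL")))
#' res <- run_scenario(one)
#' subset(res, name == "M1L")
#' @export
run_scenario <- function(s, settings = solver_settings()) {
  stopifnot(inherits(s, "cow_scenario"))
  settings$mode <- s$mode
  net0 <- .apply_edits(.scenario_base(s$base), s$edits)
  run_one <- function(net, sweep_segment, severity) {
    if (s$regulation) {
      reg <- regulate(net, s$params, settings)
      sol <- reg$solution
      terr <- .result_row(s$name, sweep_segment, severity, "territory",
                          reg$apr$territory, reg$apr$flow,
                          attach_pressure = unname(reg$perfusion_pressure),
                          cerebral_pressure = reg$apr$pressure,
                          state = reg$apr$state,
                          apr_lower = reg$apr$apr_lower,
                          apr_upper = reg$apr$apr_upper)
    } else {
      sol <- if (s$mode == "linear") solve_linear(net)
             else solve_nonlinear(net, settings)
      terr <- NULL
    }
    segs <- .result_row(s$name, sweep_segment, severity, "segment",
                        names(sol$segment_flows),
                        unname(sol$segment_flows),
                        re = unname(sol$segment_re),
                        resistance = unname(sol$segment_resistances),
                        dp = unname(sol$segment_dp))
    rbind(segs, terr)
  }
  if (is.null(s$sweep)) return(run_one(net0, NA_character_, NA_real_))
  sw <- s$sweep
  groups <- if (isTRUE(sw$simultaneous)) {
    list(list(label = paste(sw$segments, collapse = "+"),
              segments = sw$segments))
  } else {
    lapply(sw$segments, function(g) list(label = g, segments = g))
  }
  out <- list()
  for (g in groups) {
    for (sev in sw$severities) {
      net <- net0
      for (nm in g$segments) net <- apply_stenosis(net, nm, sev)
      out[[length(out) + 1L]] <- run_one(net, g$label, sev)
    }
  }
  do.call(rbind, out)
}

#' Write or read a scenario file
#'
#' Scenarios serialize to YAML or JSON (schema shipped under
#' `inst/schema/scenario-schema.json`). Custom base networks are stored by
#' path, the `"reference"` tag, or inline is not supported — export the
#' network separately with [write_cow_network()].
#'
#' @param s a [cow_scenario()].
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @param format `"yaml"` or `"json"`; default inferred from `path`.
#' @return `write_scenario()`: `path` invisibly; `read_scenario()`: a
#'   `cow_scenario`.
#' @export
write_scenario <- function(s, path, format = NULL) {
  stopifnot(inherits(s, "cow_scenario"))
  if (inherits(s$base, "cow_network"))
    stop("cannot serialize an in-memory base network; write it with ",
         "write_cow_network() and reference it by path", call. = FALSE)
  format <- .file_format(path, format)
  obj <- list(format_version = 1L, name = s$name, base = s$base,
              edits = s$edits, sweep = s$sweep, mode = s$mode,
              regulation = s$regulation,
              params = as.data.frame(s$params))
  if (format == "yaml") yaml::write_yaml(obj, path, precision = 12L)
  else jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path, format = NULL) {
  format <- .file_format(path, format)
  obj <- if (format == "yaml") yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  par <- .listdf_to_df(obj$params)
  sweep <- obj$sweep
  if (!is.null(sweep)) sweep$severities <- as.numeric(unlist(sweep$severities))
  if (!is.null(sweep)) sweep$segments <- as.character(unlist(sweep$segments))
  edits <- lapply(obj$edits, as.list)
  cow_scenario(obj$name, base = obj$base, edits = edits, sweep = sweep,
               mode = obj$mode, regulation = isTRUE(obj$regulation),
               params = autoregulation_params(par))
}
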
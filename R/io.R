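#' Write a network description file
#'
#' Serializes a network to YAML or JSON with sections `fluid`, `nodes`,
#' `segments` and `beds`. Dimensions are written in the anatomical dialect
#' (mm, mmHg, mmHg·min/ml) so the file is directly human-editable;
#' [read_cow_network()] restores an identical network. The format is
#' inferred from the file extension unless given explicitly.
#'
#' @param net a `cow_network`.
#' @param path output file path.
#' @param format `"yaml"` or `"json"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @seealso [read_cow_network()]
#' @export
write_cow_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "cow_network"))
  format <- .file_format(path, format)
  segs <- net$segments
  segs$length <- segs$length * 1e3
  segs$diameter <- segs$diameter * 1e3
  segs$curvature <- segs$curvature * 1e3
  obj <- list(
    format_version = 1L,
    fluid = list(density = net$fluid$density,
                 viscosity = net$fluid$viscosity,
                 cy_params = net$fluid$cy_params),
    nodes = net$nodes,
    segments = segs,
    beds = net$beds)
  if (format == "yaml") {
    yaml::write_yaml(obj, path, precision = 12L)
  } else {
    jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, null = "null", na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a network description file
#'
#' @param path a YAML or JSON file produced by [write_cow_network()] (or
#'   hand-written in the same layout; lengths/diameters/curvatures in mm,
#'   pressures in mmHg, bed resistances in mmHg·min/ml).
#' @param format `"yaml"` or `"json"`; default inferred from `path`.
#' @return A `cow_network`.
#' @export
read_cow_network <- function(path, format = NULL) {
  format <- .file_format(path, format)
  obj <- if (format == "yaml") yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("fluid", "nodes", "segments", "beds"))
    if (is.null(obj[[f]]))
      stop("network file lacks section '", f, "'", call. = FALSE)
  nodes <- .listdf_to_df(obj$nodes)
  if (is.null(nodes$pressure)) nodes$pressure <- NA_real_
  nodes$pressure <- as.numeric(nodes$pressure)
  segs <- .listdf_to_df(obj$segments)
  segs$length <- segs$length * 1e-3
  segs$diameter <- segs$diameter * 1e-3
  segs$curvature <- segs$curvature * 1e-3
  segs$patent <- as.logical(segs$patent)
  beds <- .listdf_to_df(obj$beds)
  if (is.null(beds$artery)) beds$artery <- NA_character_
  beds$artery <- as.character(beds$artery)
  cy <- obj$fluid$cy_params
  if (!is.null(cy) && all(is.na(unlist(cy)))) cy <- NULL
  fluid <- fluid_properties(density = obj$fluid$density,
                            viscosity = obj$fluid$viscosity,
                            cy_params = cy)
  cow_network(nodes, segs, beds, fluid)
}

# Tolerant list-to-data.frame coercion covering both serialization shapes:
# YAML column maps and JSON row lists.
.listdf_to_df <- function(x) {
  if (is.data.frame(x)) return(x)
  if (length(x) && all(vapply(x, is.atomic, logical(1))) &&
      !is.null(names(x))) {
    return(as.data.frame(x, stringsAsFactors = FALSE))
  }
  rows <- lapply(x, function(r) {
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.file_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("yaml", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) "yaml"
  else if (ext == "json") "json"
  else stop("cannot infer format from extension '", ext,
            "'; pass format = \"yaml\" or \"json\"", call. = FALSE)
}

#' Export a solution as a tidy table or JSON
#'
#' The CSV layout is one row per segment (name, signed flow in ml/min,
#' Reynolds number, resistance in mmHg·min/ml, pressure drop in mmHg) in a
#' fixed column and row order, with dot-decimal numbers regardless of
#' locale, so repeated runs diff cleanly. JSON carries the full solution
#' state including node pressures.
#'
#' @param sol a `cow_solution` (from [solve_linear()] or
#'   [solve_nonlinear()]).
#' @param path output file path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path) {
  stopifnot(inherits(sol, "cow_solution"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(sol), path, row.names = FALSE,
                     quote = FALSE)
  } else if (ext == "json") {
    obj <- list(mode = sol$mode, converged = sol$converged,
                iterations = sol$iterations,
                node_pressures = as.list(sol$node_pressures),
                segment_flows = as.list(sol$segment_flows),
                segment_re = as.list(sol$segment_re),
                segment_resistances = as.list(sol$segment_resistances),
                segment_dp = as.list(sol$segment_dp),
                bed_flows = as.list(sol$bed_flows))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else stop("path must end in .csv or .json", call. = FALSE)
  invisible(path)
}
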
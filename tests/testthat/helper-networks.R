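# Small hand-built circuits used across the test files.

# Geometry whose Hagen-Poiseuille resistance is exactly `r` mmHg.min/ml
# (diameter fixed at 1 mm, length solved from the closed form).
geom_with_hp <- function(r, fluid = fluid_properties(),
                         formula = "entrance") {
  r_si <- convert_resistance(r, "mmHg.min/ml", "Pa.s/m3")
  d <- 1e-3
  len <- r_si * pi * d^4 / (128 * fluid$viscosity)
  segment_geometry(len, d, 10e-3, formula, units = "m")
}

# Inlet -> one segment (HP resistance r1) -> terminal bed (r2, drain 0).
chain_network <- function(r1 = 0.5, r2 = 0.5, p_in = 93,
                          fluid = fluid_properties()) {
  g <- geom_with_hp(r1, fluid)
  nodes <- data.frame(id = c("in", "mid"),
                      kind = c("INLET", "TERMINAL_OUTLET"),
                      pressure = c(p_in, NA_real_),
                      stringsAsFactors = FALSE)
  segs <- data.frame(name = "S1", from = "in", to = "mid",
                     length = g$length, diameter = g$diameter,
                     curvature = g$curvature_radius, formula = g$formula,
                     patent = TRUE, stringsAsFactors = FALSE)
  beds <- data.frame(territory = "middle_L", attach = "mid",
                     artery = NA_character_, resistance = r2, drain = 0,
                     stringsAsFactors = FALSE)
  cow_network(nodes, segs, beds, fluid)
}

# Inlet -> tortuous segment -> internal node -> entrance segment -> bed.
# The scalar flow equation for this series circuit has a brute-force
# root-find oracle (see test-solver.R).
series_nonlinear_network <- function(p_in = 93, r_bed = 0.5,
                                     fluid = fluid_properties()) {
  nodes <- data.frame(id = c("in", "n1", "out"),
                      kind = c("INLET", "INTERNAL", "TERMINAL_OUTLET"),
                      pressure = c(p_in, NA_real_, NA_real_),
                      stringsAsFactors = FALSE)
  segs <- data.frame(
    name = c("SA", "SB"), from = c("in", "n1"), to = c("n1", "out"),
    length = c(100e-3, 10e-3), diameter = c(3e-3, 2e-3),
    curvature = c(12e-3, 40e-3), formula = c("tortuous", "entrance"),
    patent = TRUE, stringsAsFactors = FALSE)
  beds <- data.frame(territory = "middle_L", attach = "out",
                     artery = NA_character_, resistance = r_bed, drain = 0,
                     stringsAsFactors = FALSE)
  cow_network(nodes, segs, beds, fluid)
}

# Single fixed-pressure node carrying one autoregulated bed; the bed sees
# the fixed pressure directly, so required resistances have closed forms.
one_bed_network <- function(p_attach, territory = "middle_L") {
  nodes <- data.frame(id = "src", kind = "INLET", pressure = p_attach,
                      stringsAsFactors = FALSE)
  segs <- data.frame(name = character(), from = character(),
                     to = character(), length = numeric(),
                     diameter = numeric(), curvature = numeric(),
                     formula = character(), patent = logical(),
                     stringsAsFactors = FALSE)
  beds <- data.frame(territory = territory, attach = "src",
                     artery = NA_character_, resistance = 0.5, drain = 0,
                     stringsAsFactors = FALSE)
  cow_network(nodes, segs, beds)
}

# Hagen-Poiseuille resistances of all segments of a network (SI), for
# initializing the solver in initialization-independence checks.
hp_vector <- function(net) {
  with(net$segments,
       128 * net$fluid$viscosity * length / (pi * diameter^4))
}

mirror_name <- function(x) {
  last <- substring(x, nchar(x))
  ifelse(last == "L", paste0(substring(x, 1, nchar(x) - 1), "R"),
         ifelse(last == "R", paste0(substring(x, 1, nchar(x) - 1), "L"), x))
}
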
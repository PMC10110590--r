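test_that("a series chain solves like an Ohmic circuit", {
  net <- chain_network(r1 = 0.5, r2 = 0.5, p_in = 93)
  sol <- solve_linear(net)
  expect_equal(unname(sol$segment_flows[["S1"]]), 93, tolerance = 1e-10)
  expect_equal(unname(sol$node_pressures[["mid"]]), 46.5, tolerance = 1e-10)
  expect_true(sol$converged)
})

test_that("mirror symmetry of the reference network shows in both solvers", {
  net <- reference_network()
  for (sol in list(solve_linear(net), solve_nonlinear(net))) {
    expect_lt(abs(sol$segment_flows[["ACoA"]]), 1e-8)
    for (nm in c("ICAL", "M1L", "A1L", "P1L", "PCoAL", "P2L", "A2L", "VAL")) {
      expect_equal(unname(sol$segment_flows[[nm]]),
                   unname(sol$segment_flows[[mirror_name(nm)]]),
                   tolerance = 1e-8)
    }
  }
})

test_that("nonlinear flows are dominated by linear flows at every outlet", {
  net <- reference_network()
  lin <- solve_linear(net)
  nl <- solve_nonlinear(net)
  expect_true(all(nl$bed_flows <= lin$bed_flows))
  expect_gt(lin$segment_flows[["M1L"]], nl$segment_flows[["M1L"]])
})

test_that("zero driving pressure yields the all-zero solution", {
  net <- set_inlet_pressure(reference_network(), 10)  # equals bed drains
  sol <- solve_nonlinear(net)
  expect_true(all(abs(sol$segment_flows) < 1e-10))
  expect_true(all(abs(sol$node_pressures - 10) < 1e-10))
})

test_that("the fixed point is independent of initialization", {
  net <- reference_network()
  s1 <- solve_nonlinear(net)
  s2 <- solve_nonlinear(net, init = 2 * hp_vector(net))
  tol <- 10 * solver_settings()$rel_tolerance
  expect_equal(unname(s1$segment_flows), unname(s2$segment_flows),
               tolerance = tol)
})

test_that("the fixed point matches a brute-force root-find on a series toy network", {
  net <- series_nonlinear_network(p_in = 93, r_bed = 0.5)
  sol <- solve_nonlinear(net)
  # independent oracle: scalar flow equation DeltaP = (RA(Q)+RB(Q)+Rb) Q
  fl <- net$fluid
  gA <- segment_geometry(100, 3, 12, "tortuous")
  gB <- segment_geometry(10, 2, 40, "entrance")
  rb_si <- convert_resistance(0.5, "mmHg.min/ml", "Pa.s/m3")
  dp <- 93 * cow_constants()$mmHg_Pa
  f <- function(q) {
    dp - (segment_resistance(gA, q, fl) + segment_resistance(gB, q, fl) +
            rb_si) * q
  }
  q_star <- uniroot(f, c(1e-10, 1e-3), tol = 1e-16)$root
  q_model <- sol$segment_flows[["SA"]] * cow_constants()$mlmin_m3s
  expect_equal(q_model, q_star, tolerance = 1e-8)
  expect_equal(unname(sol$segment_flows[["SA"]]),
               unname(sol$segment_flows[["SB"]]), tolerance = 1e-10)
})

test_that("converged solutions conserve flow at every free node", {
  nets <- list(reference_network(),
               occlude(reference_network(), "ICAL"),
               occlude(reference_network(), "BA"))
  for (net in nets) {
    sol <- solve_nonlinear(net)
    res <- node_balance_residuals(sol, net)
    inflow <- sum(abs(sol$segment_flows[c("ICAL", "ICAR", "VAL", "VAR")]))
    expect_lt(attr(res, "max_abs"), 1e-9 * inflow)
  }
})

test_that("the balance audit localizes a hand-made perturbation", {
  net <- reference_network()
  sol <- solve_nonlinear(net)
  sol$segment_flows[["BA"]] <- sol$segment_flows[["BA"]] + 1
  res <- node_balance_residuals(sol, net)
  expect_equal(unname(res[["BA_orig"]]), -1, tolerance = 1e-6)
  expect_equal(unname(res[["BA_top"]]), 1, tolerance = 1e-6)
  zero <- sol
  zero$segment_flows[] <- 0
  zero$bed_flows[] <- 0
  expect_equal(attr(node_balance_residuals(zero, net), "max_abs"), 0)
})

test_that("a node cut off from every pressure boundary raises a structured error", {
  net <- reference_network()
  raw <- unclass(net)
  raw$nodes <- rbind(raw$nodes,
                     data.frame(id = c("lost_a", "lost_b"),
                                kind = "INTERNAL", pressure = NA_real_))
  raw$segments <- rbind(raw$segments,
                        data.frame(name = "LOST", from = "lost_a",
                                   to = "lost_b", length = 0.01,
                                   diameter = 0.002, curvature = 0.01,
                                   formula = "entrance", patent = TRUE))
  class(raw) <- "cow_network"
  err <- tryCatch(solve_nonlinear(raw), cow_singular_error = identity)
  expect_s3_class(err, "cow_singular_error")
  expect_setequal(err$nodes, c("lost_a", "lost_b"))
})

test_that("exhausting the iteration budget raises an error carrying the last iterate", {
  net <- reference_network()
  s <- solver_settings(rel_tolerance = 1e-14, max_iterations = 3)
  err <- tryCatch(solve_nonlinear(net, s), cow_convergence_error = identity)
  expect_s3_class(err, "cow_convergence_error")
  expect_s3_class(err$last_solution, "cow_solution")
  expect_false(err$last_solution$converged)
})

test_that("converged resistances satisfy the constitutive law R(Q) at each segment", {
  net <- reference_network()
  sol <- solve_nonlinear(net)
  fl <- net$fluid
  for (i in seq_len(nrow(net$segments))) {
    g <- with(net$segments[i, ],
              segment_geometry(length, diameter, curvature, formula,
                               units = "m"))
    q <- sol$segment_flows[[net$segments$name[i]]] * cow_constants()$mlmin_m3s
    r_formula <- convert_resistance(segment_resistance(g, q, fl),
                                    "Pa.s/m3", "mmHg.min/ml")
    dp_pred <- r_formula * sol$segment_flows[[net$segments$name[i]]]
    expect_equal(dp_pred, unname(sol$segment_dp[[net$segments$name[i]]]),
                 tolerance = 1e-6)
  }
})
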
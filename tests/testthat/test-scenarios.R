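test_that("an empty scenario reproduces the direct solver call", {
  res <- run_scenario(cow_scenario("plain"))
  sol <- solve_nonlinear(reference_network())
  expect_equal(nrow(res), 18)
  expect_equal(stats::setNames(res$flow_ml_min, res$name),
               sol$segment_flows[res$name], tolerance = 1e-12)
})

test_that("occlusion presets run and zero out the occluded vessel", {
  presets <- list(c("ICAL"), c("BA"), c("ICAL", "VAR"))
  for (p in presets) {
    s <- cow_scenario(paste(p, collapse = "+"),
                      edits = lapply(p, function(x)
                        list(op = "occlude", segment = x)))
    res <- run_scenario(s)
    expect_equal(nrow(res), 18)
    expect_true(all(res$flow_ml_min[res$name %in% p] == 0))
    expect_true(all(is.finite(res$flow_ml_min)))
  }
})

test_that("a bilateral regulated sweep emits territory records and PCoA collateral traces", {
  s <- cow_scenario("bilateral",
                    edits = list(list(op = "set_diameter",
                                      segment = "PCoAL", value = 1.2),
                                 list(op = "set_diameter",
                                      segment = "PCoAR", value = 1.2)),
                    sweep = list(segments = c("ICAL", "ICAR"),
                                 severities = seq(0, 0.8, by = 0.2),
                                 simultaneous = TRUE),
                    regulation = TRUE)
  res <- run_scenario(s)
  expect_setequal(unique(res$record), c("segment", "territory"))
  pcoa <- res[res$name == "PCoAL", ]
  expect_equal(nrow(pcoa), 5)
  # the posterior-to-anterior collateral grows as the carotids narrow
  # (PCoA positive convention is anterior->posterior, so flow turns negative)
  expect_lt(pcoa$flow_ml_min[pcoa$severity == 0.8],
            pcoa$flow_ml_min[pcoa$severity == 0])
  terr <- res[res$record == "territory", ]
  expect_true(all(c("state", "apr_lower", "apr_upper") %in% names(terr)))
  expect_true(all(terr$state[terr$severity == 0] == "WITHIN"))
  # left and right APR stay equal under the symmetric bilateral sweep
  for (sv in unique(terr$severity)) {
    l <- terr[terr$severity == sv & terr$name == "middle_L", ]
    r <- terr[terr$severity == sv & terr$name == "middle_R", ]
    expect_equal(l$apr_lower, r$apr_lower, tolerance = 1e-6)
  }
})

test_that("scenario files round-trip through YAML and reproduce identical results", {
  s <- cow_scenario("sweep",
                    edits = list(list(op = "set_diameter",
                                      segment = "ACoA", value = 0.4)),
                    sweep = list(segments = "ICAL",
                                 severities = c(0, 0.3, 0.6),
                                 simultaneous = TRUE),
                    mode = "nonlinear", regulation = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(s, path)
  s2 <- read_scenario(path)
  expect_equal(run_scenario(s2), run_scenario(s), tolerance = 1e-12)
})

test_that("solution CSV export is byte-identical across repeated runs", {
  net <- reference_network()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_solution(solve_nonlinear(net), p1)
  write_solution(solve_nonlinear(net), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(utils::read.csv(p1)), 18)
})

test_that("fixture generation is deterministic and perturbation 0 is the identity", {
  a <- generate_fixture_networks(seed = 11, count = 4, perturbation = 0.2,
                                 remove_prob = 0.5)
  b <- generate_fixture_networks(seed = 11, count = 4, perturbation = 0.2,
                                 remove_prob = 0.5)
  expect_identical(a, b)
  plain <- generate_fixture_networks(seed = 5, count = 3, perturbation = 0)
  for (net in plain) expect_identical(net, reference_network())
  expect_error(generate_fixture_networks(1, 2, perturbation = 0.7),
               "0.5")
  # the generator must not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_fixture_networks(3, 2, 0.1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the nonlinear solver converges on a family of perturbed anatomies", {
  nets <- generate_fixture_networks(seed = 42, count = 12,
                                    perturbation = 0.2, remove_prob = 0.3)
  for (net in nets) {
    expect_equal(nrow(validate_topology(net)), 0)
    sol <- solve_nonlinear(net)
    expect_true(sol$converged)
    res <- node_balance_residuals(sol, net)
    inflow <- sum(abs(sol$segment_flows[c("ICAL", "ICAR", "VAL", "VAR")]))
    expect_lt(attr(res, "max_abs"), 1e-9 * inflow)
  }
})

test_that("the validation harness recomputes errors against the bundled CFD flows", {
  v <- validate_model()
  expect_equal(nrow(v), 3)
  expect_equal(v$relative_error,
               abs(v$model_value - v$reference_value) / v$reference_value)
  expect_identical(v$pass, v$relative_error <= v$bound)
  ref <- cfd_reference_values()
  expect_setequal(ref$value, unique(v$reference_value))
})
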
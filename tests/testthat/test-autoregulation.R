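test_that("default parameters encode the per-territory targets and limits", {
  par <- default_autoregulation_params()
  expect_equal(nrow(par), 6)
  mid <- par[par$territory == "middle_L", ]
  expect_equal(mid$q_target, 162)
  expect_equal(mid$r_min, 0.32)
  expect_equal(mid$r_max, 0.90)
  ant <- par[par$territory == "anterior_R", ]
  expect_equal(c(ant$q_target, ant$r_min, ant$r_max), c(111, 0.46, 1.31))
  pos <- par[par$territory == "posterior_L", ]
  expect_equal(c(pos$q_target, pos$r_min, pos$r_max), c(120, 0.44, 1.20))
  expect_true(all(par$p_lower == 50 & par$p_upper == 150))
  # the resistance floor is the ideal characteristic at the lower limit
  expect_true(all(abs(par$p_lower / par$q_target - par$r_min) /
                    par$r_min <= 0.10))
  expect_error(autoregulation_params(transform(par, r_min = r_max)),
               "r_min < r_max")
})

test_that("the reference network is fully regulated at 93 mmHg inlets", {
  reg <- regulate(reference_network())
  expect_true(all(reg$regulation_state == "WITHIN"))
  par <- default_autoregulation_params()
  for (t in par$territory) {
    expect_equal(unname(reg$solution$bed_flows[[t]]),
                 par$q_target[par$territory == t], tolerance = 1e-6)
  }
  expect_true(all(reg$apr$apr_lower > 0 & reg$apr$apr_upper > 0))
})

test_that("hypotension drives every bed to maximal dilation", {
  net <- set_inlet_pressure(reference_network(), 30)
  reg <- regulate(net)
  expect_true(all(reg$regulation_state == "BELOW_LOWER"))
  par <- default_autoregulation_params()
  expect_equal(unname(reg$bed_resistances[par$territory]),
               par$r_min, tolerance = 1e-6)
  expect_true(all(reg$apr$apr_lower < 0))
})

test_that("a single bed at fixed pressure follows the clipped ideal characteristic", {
  reg <- regulate(one_bed_network(45))
  expect_identical(unname(reg$regulation_state), "BELOW_LOWER")
  expect_equal(unname(reg$bed_resistances), 0.32, tolerance = 1e-8)
  expect_equal(unname(reg$required_resistance), 45 / 162, tolerance = 1e-8)
  expect_equal(unname(reg$solution$bed_flows), 45 / 0.32, tolerance = 1e-6)

  # inside the clip the bed delivers the target exactly
  reg2 <- regulate(one_bed_network(70))
  expect_identical(unname(reg2$regulation_state), "WITHIN")
  expect_equal(unname(reg2$solution$bed_flows), 162, tolerance = 1e-6)

  # hypertension clips at r_max
  reg3 <- regulate(one_bed_network(160))
  expect_identical(unname(reg3$regulation_state), "ABOVE_UPPER")
  expect_equal(unname(reg3$bed_resistances), 0.90, tolerance = 1e-8)
})

test_that("APR components are the signed margins to the limits", {
  for (case in list(c(70, 20, 80), c(50, 0, 100), c(45, -5, 105))) {
    reg <- regulate(one_bed_network(case[1]))
    apr <- compute_apr(reg)
    expect_equal(apr$apr_lower, case[2], tolerance = 1e-9)
    expect_equal(apr$apr_upper, case[3], tolerance = 1e-9)
  }
})

test_that("regulated flow plateaus across inlet pressure while resistances track it", {
  rbed <- c()
  for (p in seq(75, 120, by = 15)) {
    reg <- regulate(set_inlet_pressure(reference_network(), p))
    expect_true(all(reg$regulation_state == "WITHIN"))
    expect_equal(unname(reg$solution$bed_flows[["middle_L"]]), 162,
                 tolerance = 1e-6)
    expect_equal(unname(reg$solution$bed_flows[["posterior_R"]]), 120,
                 tolerance = 1e-6)
    rbed <- c(rbed, reg$bed_resistances[["middle_L"]])
  }
  expect_true(all(diff(rbed) > 0))
})

test_that("regulation state agrees with a recomputation from converged pressures", {
  par <- default_autoregulation_params()
  nets <- list(reference_network(),
               apply_stenosis(set_diameter(reference_network(), "ACoA", 0.4),
                              "ICAL", 0.5),
               set_inlet_pressure(reference_network(), 40))
  for (net in nets) {
    reg <- regulate(net)
    for (j in seq_len(nrow(net$beds))) {
      t <- net$beds$territory[j]
      p <- reg$solution$node_pressures[[net$beds$attach[j]]]
      i <- match(t, par$territory)
      req <- (p - par$drain[i]) / par$q_target[i]
      state <- if (req < par$r_min[i]) "BELOW_LOWER"
               else if (req > par$r_max[i]) "ABOVE_UPPER" else "WITHIN"
      expect_identical(unname(reg$regulation_state[[t]]), state)
    }
  }
})

test_that("stenosing a vessel irrelevant to a territory never breaks its regulation", {
  net <- reference_network()
  sev <- find_autoregulation_exit(net, stenosed_segment = "A2R",
                                  territory = "middle_L",
                                  coarse_step = 0.25)
  expect_true(is.na(sev))
  expect_error(find_autoregulation_exit(net, stenosed_segment = "XYZ",
                                        territory = "middle_L"),
               "unknown segment")
  expect_error(find_autoregulation_exit(net, stenosed_segment = "ICAL",
                                        territory = "occipital"),
               "unknown territory")
})

test_that("the lower pressure reserve decays monotonically along an ICA stenosis sweep", {
  net <- set_diameter(reference_network(), "ACoA", 0.4)
  apr_l <- vapply(seq(0, 0.6, by = 0.1), function(sev) {
    reg <- regulate(apply_stenosis(net, "ICAL", sev))
    reg$apr$apr_lower[reg$apr$territory == "middle_L"]
  }, numeric(1))
  expect_true(all(diff(apr_l) < 0))
})
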
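test_that("RC discharge follows the closed form", {
  fx <- make_fixtures("rc")
  run <- integrate_circuit(fx$circuit, solver_config(parasitic_capacitance = 0),
                           c(0, 5), init = fx$init)
  expect_lt(max(abs(run$probes$p$v - fx$reference(run$probes$p$t))), 1e-4)
})

test_that("a resistor between a unit source and ground carries unit flow", {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "s")
  ck <- add_pressure_source(ck, "src", "s", 1)
  ck <- add_resistor(ck, "R", "s", "ground", 1)
  ck <- add_probe(ck, "q", "flow", "R")
  run <- integrate_circuit(ck, solver_config(), c(0, 0.01))
  expect_equal(run$probes$q$v, rep(1, length(run$probes$q$v)))
})

test_that("Windkessel circuits match their analytic impedances", {
  # 2-element: steady-state amplitude within 1% of |Z(w)| q0 at three rates
  for (f in c(0.5, 1.25, 5)) {
    fx <- make_fixtures("windkessel2", freq = f)
    t_end <- fx$settle + 4 / f
    run <- integrate_circuit(fx$circuit,
                             solver_config(rel_tol = 1e-8, abs_tol = 1e-10),
                             c(0, t_end))
    sel <- run$probes$p$t > fx$settle
    amp <- (max(run$probes$p$v[sel]) - min(run$probes$p$v[sel])) / 2
    expect_lt(abs(amp - fx$reference) / fx$reference, 0.01)
  }
  # 3-element: DC inlet pressure Q0 (Rp + Rd) + P_out
  fx <- make_fixtures("windkessel3")
  run <- integrate_circuit(fx$circuit, solver_config(), c(0, fx$settle))
  expect_equal(tail(run$probes$p_in$v, 1), fx$reference, tolerance = 1e-4)
})

test_that("the smoothed diode is strongly asymmetric with bounded leakage", {
  flow_at <- function(bias) {
    ck <- circuit()
    ck <- add_node(ck, "ground", ground = TRUE)
    ck <- add_node(ck, "s")
    ck <- add_pressure_source(ck, "src", "s", bias)
    ck <- add_diode(ck, "D", "s", "ground")
    ck <- add_probe(ck, "q", "flow", "D")
    integrate_circuit(ck, solver_config(), c(0, 0.01))$probes$q$v[2]
  }
  expect_gt(abs(flow_at(100) / flow_at(-100)), 1e4)
  # reverse leakage bounded by g_off * |dP| (series resistor in the branch)
  fx <- make_fixtures("diode_pump", bias = -1)
  run <- integrate_circuit(fx$circuit, solver_config(), c(0, 0.01))
  expect_lte(max(abs(run$probes$q$v)), fx$reference(solver_config()$g_off))
})

test_that("undriven circuits dissipate energy and driven ones are refused", {
  fx <- make_fixtures("rc")
  run <- integrate_circuit(fx$circuit, solver_config(parasitic_capacitance = 0),
                           c(0, 3), init = fx$init)
  expect_true(check_passivity(run)$passive)
  # damped LC oscillator: decaying oscillation, energy non-increasing
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "n")
  ck <- add_inductor(ck, "L", "n", "ground", 1, series_r = 0.2)
  ck <- add_capacitor(ck, "C", "n", value = 1)
  ck <- add_probe(ck, "p", "pressure", "n")
  run <- integrate_circuit(ck, solver_config(rel_tol = 1e-9,
                                             abs_tol = 1e-12,
                                             parasitic_capacitance = 0),
                           c(0, 10), init = c(n = 1))
  pp <- check_passivity(run, tol = 1e-5)
  expect_true(pp$passive)
  expect_lt(max(run$probes$p$v[run$probes$p$t > 5]), 0.7)  # it decays
  # driven circuit: precondition violated
  fx3 <- make_fixtures("windkessel3")
  run3 <- integrate_circuit(fx3$circuit, solver_config(), c(0, 0.1))
  expect_error(check_passivity(run3), "sources")
})

test_that("topology violations are reported with the offending nodes", {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  expect_error(add_node(ck, "ground"), "duplicate")
  ck <- add_node(ck, "a")
  expect_error(validate_circuit(circuit()), "ground")
  # floating node
  ck2 <- add_node(ck, "b")
  ck2 <- add_resistor(ck2, "R", "a", "ground", 1)
  expect_error(validate_circuit(ck2), "b")
  # capacitor-only loop between two nodes
  ck3 <- add_resistor(ck, "R", "a", "ground", 1)
  ck3 <- add_node(ck3, "c")
  ck3 <- add_resistor(ck3, "Rc", "c", "ground", 1)
  ck3 <- add_capacitor(ck3, "C1", "a", neg = "c", value = 1)
  ck3 <- add_capacitor(ck3, "C2", "a", neg = "c", value = 2)
  expect_error(validate_circuit(ck3), "loop")
  # unreachable from any source
  ck4 <- add_node(ck, "d")
  ck4 <- add_resistor(ck4, "Rd", "d", "a", 1)
  ck4 <- add_capacitor(ck4, "Ca", "a", value = 1)
  ck4 <- add_pressure_source(ck4, "P", "a", 1)
  expect_silent(validate_circuit(ck4))
})

test_that("halving the solver tolerances leaves probes unchanged to 0.1%", {
  fx <- make_fixtures("windkessel3")
  run1 <- integrate_circuit(fx$circuit, solver_config(), c(0, 2))
  run2 <- integrate_circuit(fx$circuit,
                            solver_config(rel_tol = 5e-7, abs_tol = 5e-9),
                            c(0, 2))
  rel <- abs(run1$probes$p_in$v - run2$probes$p_in$v) /
    pmax(abs(run2$probes$p_in$v), 1)
  expect_lt(max(rel), 1e-3)
})

test_that("integration is bit-identical across repeated runs", {
  fx <- make_fixtures("windkessel2")
  r1 <- integrate_circuit(fx$circuit, solver_config(), c(0, 1))
  r2 <- integrate_circuit(fx$circuit, solver_config(), c(0, 1))
  expect_identical(r1$probes$p$v, r2$probes$p$v)
})
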
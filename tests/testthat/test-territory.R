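# algebraic DC solution of the standalone territory chain (resistive
# divider with the AVA bridge), independent of the integrator
territory_dc_oracle <- function(territory, inlet = 90, icp = 10) {
  ps <- artery_parameter_set("scenario1")
  row <- terminal_row(ps, territory)
  rt <- microcirculation_ratios()
  Rd <- row$Rd_SI
  ra <- rt$r_arteriole * Rd / 2; rc <- rt$r_capillary * Rd
  rv <- rt$r_venule * Rd / 2; rava <- rt$rava_multiplier * 2 * ra
  pin <- mmHg_to_Pa(inlet); pv <- mmHg_to_Pa(5)
  # unknowns: pa, ma, n1, n2, n3
  A <- matrix(0, 5, 5); b <- numeric(5)
  g <- function(i, j, G) {
    if (i > 0) { A[i, i] <<- A[i, i] + G; if (j > 0) A[i, j] <<- A[i, j] - G }
    if (j > 0) { A[j, j] <<- A[j, j] + G; if (i > 0) A[j, i] <<- A[j, i] - G }
  }
  g(1, 2, 1 / ra); g(2, 3, 1 / ra); g(3, 4, 1 / rc); g(4, 5, 1 / rv)
  g(2, 5, 1 / rava)
  A[1, 1] <- A[1, 1] + 1 / row$Rp_SI; b[1] <- pin / row$Rp_SI
  A[5, 5] <- A[5, 5] + 1 / rv; b[5] <- pv / rv
  p <- solve(A, b)
  icp_pa <- mmHg_to_Pa(icp)
  list(nodes = p, ppg = (p[4] - icp_pa) + (p[5] - icp_pa) + (pv - icp_pa))
}

test_that("territory chains partition the terminal distal values exactly", {
  ps <- artery_parameter_set("scenario1")
  rt <- microcirculation_ratios()
  for (terr in c("ACA-L", "MCA-L", "PCA-L")) {
    ck <- build_territory(terr, ps, rt)
    row <- terminal_row(ps, terr)
    ids <- vapply(ck$elements, `[[`, "", "id")
    chain <- paste0("t_", c("RA1", "RA2", "RC", "RV2", "RV1"))
    rsum <- sum(vapply(ck$elements[ids %in% chain], `[[`, 0, "value"))
    expect_equal(rsum, row$Rd_SI, tolerance = 1e-3)
    caps <- ck$elements[grepl("^t_C", ids)]
    csum <- sum(vapply(caps, function(e) e$law$value, 0))
    expect_equal(csum, row$C_SI, tolerance = 1e-3)
  }
  expect_error(build_territory("XYZ-L"), "territory")
})

test_that("the DC operating point matches the algebraic divider", {
  ck <- build_territory("ACA-L")
  run <- integrate_circuit(ck, solver_config(output_rate = 100), c(0, 30))
  oracle <- territory_dc_oracle("ACA-L")
  ppg <- ppg_signal(run, "ppg")
  expect_equal(tail(ppg$v, 1), oracle$ppg, tolerance = 1e-4)
  expect_equal(tail(run$probes$prearteriole$v, 1), oracle$nodes[1],
               tolerance = 1e-4)
})

test_that("an open anastomosis reduces to the series chain", {
  rt <- microcirculation_ratios()
  rt$rava_multiplier <- 1e9   # effectively open circuit
  ck <- build_territory("PCA-L", ratios = rt)
  ck <- add_probe(ck, "q_chain", "flow", "t_RC")
  run <- integrate_circuit(ck, solver_config(output_rate = 100), c(0, 30))
  row <- terminal_row(artery_parameter_set("scenario1"), "PCA-L")
  series_q <- (mmHg_to_Pa(90) - mmHg_to_Pa(5)) / (row$Rp_SI + row$Rd_SI)
  expect_equal(tail(run$probes$q_chain$v, 1), series_q, tolerance = 1e-4)
  ck <- add_probe(ck, "q_ava", "flow", "t_RAVA")
  run <- integrate_circuit(ck, solver_config(output_rate = 100), c(0, 30))
  expect_lt(abs(tail(run$probes$q_ava$v, 1)), 1e-6 * series_q)
})

test_that("the PPG is invariant to a common offset of inlet and ICP", {
  base <- build_territory("MCA-L", inlet_pressure = 90, icp_pressure = 10)
  shift <- build_territory("MCA-L", inlet_pressure = 90 + 100 / 133.322,
                           icp_pressure = 10 + 100 / 133.322)
  # the venous source must shift too for a pure common-mode displacement
  ids <- vapply(shift$elements, `[[`, "", "id")
  shift$elements[[match("src_venous", ids)]]$value <-
    mmHg_to_Pa(5) + 100
  r1 <- integrate_circuit(base, solver_config(output_rate = 100), c(0, 20))
  r2 <- integrate_circuit(shift, solver_config(output_rate = 100), c(0, 20))
  p1 <- ppg_signal(r1, "ppg"); p2 <- ppg_signal(r2, "ppg")
  expect_equal(tail(p1$v, 1), tail(p2$v, 1), tolerance = 1e-6)
})

test_that("capillary-only and summed PPG probes are both available", {
  sim <- normal_sim()
  full <- sim$ppg[["MCA-L"]]
  cc <- ppg_signal(sim, "ppg_MCA-L", probe = "capillary")
  expect_lt(max(cc$v), max(full$v))
  expect_equal(length(cc$v), length(full$v))
})
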
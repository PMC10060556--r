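test_that("compiled and reference derivative evaluators agree exactly", {
  net <- build_network(40)
  ck <- couple(net)
  sys <- assemble(ck)
  expect_false(is.null(sys$cpp_spec))
  ptr <- circuit_model_new(sys$cpp_spec)
  set.seed(42)
  for (t in c(0.11, 3.21, 10.05)) {
    y <- c(mmHg_to_Pa(runif(sys$n_free, 2, 120)),
           runif(sys$n_ind, -1e-5, 1e-5))
    a <- sys$rhs(t, y, NULL)[[1]]
    b <- circuit_model_rhs(ptr, t, y)
    expect_lt(max(abs(a - b) / (abs(a) + 1e-9)), 1e-12)
  }
})

test_that("the coupled simulation reaches a periodic regime after 10 s", {
  sim <- normal_sim()
  T <- 0.8
  cyc <- function(ts, k) {
    sel <- ts$t >= 10 + k * T - 1e-9 & ts$t < 10 + (k + 1) * T - 1e-9
    ts$v[sel]
  }
  for (terr in names(sim$ppg)) {
    c1 <- cyc(sim$ppg[[terr]], 0); c2 <- cyc(sim$ppg[[terr]], 1)
    n <- min(length(c1), length(c2))
    rms <- sqrt(mean((c1[1:n] - c2[1:n])^2))
    expect_lt(rms / mean(c1), 0.01)
  }
  # ICP drifts slowly by design (craniospinal charging); successive cycles
  # still agree to a few percent
  i1 <- cyc(sim$probes$icp, 0); i2 <- cyc(sim$probes$icp, 1)
  n <- min(length(i1), length(i2))
  expect_lt(sqrt(mean((i1[1:n] - i2[1:n])^2)) / mean(i1), 0.05)
})

test_that("the simulated PPG has no sharp high-frequency content", {
  sim <- normal_sim()
  for (terr in names(sim$ppg)) {
    ts <- sim$ppg[[terr]]
    sel <- ts$t >= 10 & ts$t < 13.2
    v <- ts$v[sel] - mean(ts$v[sel])
    sp <- Mod(stats::fft(v))^2
    freq <- seq_along(sp) - 1
    freq <- freq / 3.2                      # bins of 1/3.2 Hz
    half <- seq_len(floor(length(v) / 2))
    hi <- sum(sp[half][freq[half] > 10])
    expect_lt(hi / sum(sp[half]), 0.01)
  }
})

test_that("the physiological operating point is sane", {
  sim <- normal_sim()
  s <- summary(sim)
  expect_gt(s$aortic_root_mmHg["mean"], 70)
  expect_lt(s$aortic_root_mmHg["mean"], 110)
  expect_gt(s$icp_mmHg["mean"], 8)
  expect_lt(s$icp_mmHg["mean"], 15)
  f <- s$features
  expect_true(all(f$mean[f$signal == "ppg"] > 0))
  expect_true(all(is.finite(unlist(f[, feature_names()]))))
})

test_that("simulation output is deterministic to the last bit", {
  a <- simulate_cerebral(40, ratio_cd = 0.5, territories = "MCA-L",
                         duration = 11.5)
  b <- simulate_cerebral(40, ratio_cd = 0.5, territories = "MCA-L",
                         duration = 11.5)
  expect_identical(a$probes$icp$v, b$probes$icp$v)
  expect_identical(a$ppg[["MCA-L"]]$v, b$ppg[["MCA-L"]]$v)
})

test_that("circuits survive a serialisation round trip", {
  fx <- make_fixtures("windkessel3")
  tmp <- tempfile(fileext = ".txt")
  write_circuit(fx$circuit, tmp)
  restored <- read_circuit(tmp)
  r1 <- integrate_circuit(fx$circuit, solver_config(), c(0, 1))
  r2 <- integrate_circuit(restored, solver_config(), c(0, 1))
  expect_identical(r1$probes$p_in$v, r2$probes$p_in$v)
  # nonlinear laws and the coupled topology survive too
  net <- couple(build_network(40))
  net <- add_probe(net, "icp", "pressure", "icp")
  tmp2 <- tempfile(fileext = ".txt")
  write_circuit(net, tmp2)
  net2 <- read_circuit(tmp2)
  s1 <- assemble(net); s2 <- assemble(net2)
  y <- c(mmHg_to_Pa(seq(5, 120, length.out = s1$n_free)),
         rep(1e-6, s1$n_ind))
  expect_equal(s1$rhs(0.3, y, NULL)[[1]], s2$rhs(0.3, y, NULL)[[1]],
               tolerance = 1e-12)
  # arbitrary closures have no text form
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "n")
  ck <- add_flow_source(ck, "Q", "n", value = function(t) sin(t))
  ck <- add_resistor(ck, "R", "n", "ground", 1)
  expect_error(write_circuit(ck, tempfile()), "serialise")
})
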
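# these tests share one full default grid (12 coupled 30 s runs, computed
# once per session in helper-simulations.R)

test_that("the default grid produces the full record structure", {
  g <- full_grid()
  expect_equal(nrow(g$failed), 0L)
  expect_equal(nrow(g$icp_summary), 12L)          # 3 ages x 4 conditions
  expect_equal(nrow(g$features), 36L)             # x 3 territories
  expect_setequal(unique(g$features$territory),
                  c("ACA-L", "MCA-L", "PCA-L"))
  sh <- g$relative_differences
  expect_equal(nrow(sh), 3L * 3L * 8L)            # age x territory x feature
})

test_that("mean ICP rises as intracranial capacitance falls, at every age", {
  g <- full_grid()
  for (age in unique(g$icp_summary$age)) {
    sub <- g$icp_summary[g$icp_summary$age == age, ]
    sub <- sub[order(-sub$ratio_cd), ]
    expect_true(all(diff(sub$icp_mean) > 0))
    # pulse amplitude grows too
    expect_true(all(diff(sub$icp_amplitude) > 0))
  }
})

test_that("mean ICP is almost independent of age at fixed capacitance", {
  g <- full_grid()
  for (r in unique(g$icp_summary$ratio_cd)) {
    sub <- g$icp_summary[g$icp_summary$ratio_cd == r, ]
    expect_lt(max(sub$icp_mean) - min(sub$icp_mean), 1)
  }
})

test_that("PPG value features fall strictly as ICP rises", {
  g <- full_grid()
  for (age in unique(g$features$age)) {
    for (terr in unique(g$features$territory)) {
      sub <- g$features[g$features$age == age &
                          g$features$territory == terr, ]
      sub <- sub[order(-sub$ratio_cd), ]
      expect_true(all(diff(sub$maximum) < 0))
      expect_true(all(diff(sub$minimum) < 0))
      expect_true(all(diff(sub$mean) < 0))
    }
  }
})

test_that("PI, RI and MMR increase with age in every territory", {
  g <- full_grid()
  f <- g$features[g$features$ratio_cd == 1, ]
  for (terr in unique(f$territory)) {
    sub <- f[f$territory == terr, ]
    sub <- sub[order(sub$age), ]
    expect_true(all(diff(sub$PI) > 0))
    expect_true(all(diff(sub$RI) > 0))
    expect_true(all(diff(sub$MMR) > 0))
  }
})

test_that("the MCA territory is the least pulsatile at every age", {
  g <- full_grid()
  f <- g$features[g$features$ratio_cd == 1, ]
  for (age in unique(f$age)) {
    sub <- f[f$age == age, ]
    for (feat in c("PI", "RI", "MMR")) {
      mca <- sub[[feat]][sub$territory == "MCA-L"]
      expect_lt(mca, sub[[feat]][sub$territory == "ACA-L"])
      expect_lt(mca, sub[[feat]][sub$territory == "PCA-L"])
    }
  }
})

test_that("grid outputs are byte-identical across repeated runs", {
  cfg <- scenario_config(ages = 40, ratio_cd_list = c(1, 0.5),
                         territories = "MCA-L", duration = 11.5)
  d1 <- tempfile(); d2 <- tempfile()
  run_grid(cfg, out_dir = d1)
  run_grid(cfg, out_dir = d2)
  for (f in c("features.csv", "icp_summary.csv",
              "relative_differences.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("the abstract-grid preset swaps in the 20% reduction condition", {
  cfg <- scenario_config(abstract_grid = TRUE)
  expect_equal(cfg$ratio_cd_list, c(1, 0.8, 0.5, 0.25))
  expect_error(scenario_config(duration = 5), "duration")
  expect_error(scenario_config(ratio_cd_list = c(1, 0)), "ratio")
})
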
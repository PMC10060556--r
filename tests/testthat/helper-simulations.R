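# Shared, memoised simulation results: the expensive coupled runs are
# computed once per session and reused across test files.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# one normal-condition coupled run (short, for waveform-level checks)
normal_sim <- function() {
  cached("normal_sim", simulate_cerebral(40, ratio_cd = 1, duration = 14))
}

# the full default study grid (ages 20/40/60 x ratios 1/.75/.5/.25, 30 s
# runs) shared by the trend and acceptance tests
full_grid <- function() {
  cached("full_grid", run_grid(scenario_config()))
}

shape_features <- c("min_to_max_time", "PI", "RI", "MMR")

# features of one territory across the four conditions, as cycle_features
territory_feature_sets <- function(grid, age, territory) {
  sub <- grid$features[grid$features$age == age &
                         grid$features$territory == territory, ]
  sub <- sub[order(-sub$ratio_cd), ]
  lapply(seq_len(nrow(sub)), function(i) {
    structure(as.list(sub[i, c("maximum", "minimum", "mean", "amplitude",
                               "min_to_max_time", "PI", "RI", "MMR")]),
              class = "cycle_features")
  })
}
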
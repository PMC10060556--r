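#' Scenario configuration for the simulation grid
#'
#' Describes one full study: the ages, intracranial capacitance-reduction
#' ratios and cerebral perfusion territories to simulate, the run length and
#' measurement start, the cardiac settings and the parameter set.  The
#' defaults reproduce the shipped study conditions: ages 20/40/60 years,
#' capacitance reductions 0/25/50/75% (`ratio_cd` 1/0.75/0.5/0.25), the
#' three left-side territories, 30 s runs with features measured in the
#' first cardiac cycle after 10 s at a heart period of 0.8 s.  The preset
#' `abstract_grid = TRUE` swaps the condition list for 0/20/50/75%.
#'
#' @param ages ages in years.
#' @param ratio_cd_list capacitance-reduction ratios in (0, 1].
#' @param territories cerebral territories to simulate.
#' @param duration simulation length, s (must exceed `measure_after` + `T`).
#' @param measure_after measurement start, s.
#' @param heart_period cardiac period T, s.
#' @param stroke_volume stroke volume, m^3.
#' @param systolic_fraction systolic fraction of the cardiac period.
#' @param parameter_set parameter-set name for [artery_parameter_set()].
#' @param icp_parameter_file optional path for [icp_parameters()].
#' @param ratios_file optional path for [microcirculation_ratios()].
#' @param abstract_grid use the 0/20/50/75% condition preset.
#' @param solver a [solver_config()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(ages = c(20, 40, 60),
                            ratio_cd_list = c(1, 0.75, 0.5, 0.25),
                            territories = c("ACA-L", "MCA-L", "PCA-L"),
                            duration = 30, measure_after = 10,
                            heart_period = 0.8, stroke_volume = 85e-6,
                            systolic_fraction = 0.35,
                            parameter_set = "scenario1",
                            icp_parameter_file = NULL, ratios_file = NULL,
                            abstract_grid = FALSE,
                            solver = solver_config()) {
  if (abstract_grid) ratio_cd_list <- c(1, 0.8, 0.5, 0.25)
  stopifnot(all(ratio_cd_list > 0), all(ratio_cd_list <= 1),
            duration > measure_after + heart_period)
  for (a in ages) check_age(a)
  cfg <- list(ages = ages, ratio_cd_list = ratio_cd_list,
              territories = territories, duration = duration,
              measure_after = measure_after, heart_period = heart_period,
              stroke_volume = stroke_volume,
              systolic_fraction = systolic_fraction,
              parameter_set = parameter_set,
              icp_parameter_file = icp_parameter_file,
              ratios_file = ratios_file, solver = solver)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

# deterministic polynomial hash of the deparsed configuration
config_hash <- function(cfg) {
  cfg$hash <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full scenario grid
#'
#' Simulates every (age, ratio_cd) combination of the configuration (one
#' coupled run each; all territories share a run), extracts the eight PPG
#' waveform features and the ICP cycle summary from the first cardiac cycle
#' after `measure_after`, and computes the relative differences of the
#' shape-relevant features across the capacitance conditions for each age
#' and territory.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   `icp_summary.csv` and `relative_differences.csv` (9 significant digits,
#'   a `# config_hash:` header line for provenance).
#' @param verbose print per-run progress lines.
#' @return An object of class `sim_grid`: `features` (one row per run and
#'   territory), `icp_summary` (one row per run), `relative_differences`
#'   (one row per age, territory and shape feature), `failed` (data frame of
#'   failed runs, normally empty) and the configuration.
#' @export
run_grid <- function(config = scenario_config(), out_dir = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  pset <- artery_parameter_set(config$parameter_set)
  icp_p <- icp_parameters(config$icp_parameter_file)
  ratios <- microcirculation_ratios(config$ratios_file)
  feat <- list(); icp_rows <- list(); failed <- list()
  for (age in config$ages) {
    for (r in config$ratio_cd_list) {
      tag <- sprintf("age %g, ratio_cd %g", age, r)
      res <- try(simulate_cerebral(
        age, ratio_cd = r, territories = config$territories,
        duration = config$duration, measure_after = config$measure_after,
        heart_period = config$heart_period,
        stroke_volume = config$stroke_volume,
        systolic_fraction = config$systolic_fraction,
        pset = pset, icp_params = icp_p, ratios = ratios,
        solver = config$solver), silent = TRUE)
      if (inherits(res, "try-error")) {
        failed[[tag]] <- data.frame(age = age, ratio_cd = r,
                                    error = conditionMessage(attr(res, "condition")),
                                    stringsAsFactors = FALSE)
        if (verbose) cat("FAILED ", tag, "\n")
        next
      }
      f <- features(res)
      feat[[tag]] <- f[f$signal == "ppg", ]
      icp <- f[f$signal == "icp", ]
      icp_rows[[tag]] <- data.frame(age = age, ratio_cd = r,
                                    icp_max = icp$maximum,
                                    icp_min = icp$minimum,
                                    icp_mean = icp$mean,
                                    icp_amplitude = icp$amplitude,
                                    stringsAsFactors = FALSE)
      if (verbose) {
        cat(sprintf("%s: mean ICP %.2f mmHg\n", tag, icp$mean))
      }
    }
  }
  features_df <- do.call(rbind, c(feat, list(make.row.names = FALSE)))
  icp_df <- do.call(rbind, c(icp_rows, list(make.row.names = FALSE)))
  rel <- grid_relative_differences(features_df, config)
  out <- structure(list(features = features_df, icp_summary = icp_df,
                        relative_differences = rel,
                        failed = if (length(failed)) {
                          do.call(rbind, failed)
                        } else {
                          data.frame(age = numeric(), ratio_cd = numeric(),
                                     error = character())
                        },
                        config = config),
                   class = "sim_grid")
  if (!is.null(out_dir)) write_grid(out, out_dir)
  out
}

grid_relative_differences <- function(features_df, config) {
  rows <- list()
  for (age in unique(features_df$age)) {
    for (terr in unique(features_df$territory)) {
      sub <- features_df[features_df$age == age &
                           features_df$territory == terr, ]
      if (nrow(sub) < 2L) next
      cfs <- lapply(seq_len(nrow(sub)), function(i) {
        structure(as.list(sub[i, feature_names()]), class = "cycle_features")
      })
      rd <- relative_difference_table(cfs, features = feature_names())
      rd$age <- age; rd$territory <- terr
      rows[[paste(age, terr)]] <- rd[, c("age", "territory", "feature",
                                         "rel_diff_pct")]
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_grid_csv <- function(df, file, hash) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 9, format = "g"))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

write_grid <- function(grid, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- grid$config$hash
  write_grid_csv(grid$features, file.path(out_dir, "features.csv"), h)
  write_grid_csv(grid$icp_summary, file.path(out_dir, "icp_summary.csv"), h)
  write_grid_csv(grid$relative_differences,
                 file.path(out_dir, "relative_differences.csv"), h)
  invisible(out_dir)
}

#' @export
print.sim_grid <- function(x, ...) {
  cat("Simulation grid: ", nrow(x$icp_summary), " runs (",
      length(x$config$ages), " ages x ", length(x$config$ratio_cd_list),
      " conditions), ", nrow(x$features), " territory-feature rows\n",
      sep = "")
  if (nrow(x$failed)) cat(nrow(x$failed), "runs FAILED\n")
  cat("Cycle-mean ICP by condition [mmHg]:\n")
  print(round(stats::xtabs(icp_mean ~ age + ratio_cd, data = x$icp_summary),
              2))
  sh <- x$relative_differences[
    x$relative_differences$feature %in% shape_feature_names(), ]
  cat(sprintf("Max shape-feature relative difference: %.2f%%\n",
              max(sh$rel_diff_pct, na.rm = TRUE)))
  invisible(x)
}
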
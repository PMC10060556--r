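#' Simulate coupled ICP and cerebral PPG signals
#'
#' The package's main entry point: builds the cardiocerebral artery network
#' for the requested age, couples it to the intracranial pressure circuit
#' (scaled by the capacitance-reduction ratio) and to the per-territory
#' microcirculation models, integrates the monolithic stiff ODE system and
#' returns the simulated signals.  By default each run lasts 30 s with
#' signals sampled at 1 kHz and all waveform measurements are taken from the
#' first cardiac cycle after 10 s, discarding the initialization transient
#' (nodes start from uniform 80 mmHg arterial / 5 mmHg venous-intracranial
#' pressure and zero flow).
#'
#' @param age age in years (20--70).
#' @param ratio_cd intracranial capacitance-reduction ratio in (0, 1]
#'   (1 = normal, 0.5 = 50\% reduction, 0.25 = 75\% reduction).
#' @param territories cerebral perfusion territories to simulate PPG in.
#' @param duration simulation length, s.
#' @param measure_after waveform measurements start at the first cycle after
#'   this time, s.
#' @param heart_period cardiac period T, s.
#' @param stroke_volume stroke volume, m^3.
#' @param systolic_fraction systolic fraction of the cardiac period.
#' @param pset an [artery_parameter_set()].
#' @param icp_params an [icp_parameters()] list.
#' @param ratios a [microcirculation_ratios()] list.
#' @param solver a [solver_config()].
#' @param ppg_probe `"sum"` (all three capacitance elements) or
#'   `"capillary"` (capillary element only).
#' @return An object of class `cerebral_sim` with the probe time series
#'   (`$probes`), per-territory PPG signals (`$ppg`), the scenario
#'   configuration (`$config`) and solver diagnostics.  Methods: `print`,
#'   `summary`, `plot`, [features()].
#' @seealso [run_grid()] for the full scenario grid.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cerebral(40, ratio_cd = 1, duration = 12)
#' summary(sim)
#' }
simulate_cerebral <- function(age, ratio_cd = 1,
                              territories = c("ACA-L", "MCA-L", "PCA-L"),
                              duration = 30, measure_after = 10,
                              heart_period = 0.8, stroke_volume = 85e-6,
                              systolic_fraction = 0.35,
                              pset = artery_parameter_set("scenario1"),
                              icp_params = icp_parameters(),
                              ratios = microcirculation_ratios(),
                              solver = solver_config(),
                              ppg_probe = c("sum", "capillary")) {
  ppg_probe <- match.arg(ppg_probe)
  if (duration <= measure_after + heart_period) {
    stop("'duration' must exceed 'measure_after' plus one heart period",
         call. = FALSE)
  }
  net <- build_network(age, pset, heart_period, stroke_volume,
                       systolic_fraction)
  ck <- couple(net, icp_params, ratio_cd, pset, ratios, territories)
  ck <- add_probe(ck, "p_root", "pressure", "root")
  ck <- add_probe(ck, "p_ica_l", "pressure", "ica_e_l")
  ck <- add_probe(ck, "icp", "pressure", "icp")
  ck <- add_probe(ck, "q_csf_formation", "flow", "D_csf_form")
  ck <- add_probe(ck, "q_csf_outflow", "flow", "D_csf_out")
  for (terr in territories) {
    tn <- terminal_row(pset, terr)$name
    tag <- paste0("ppg_", terr)
    ck <- add_probe(ck, paste0(tag, "_cc"), "transmural",
                    paste0("t_", tn, "_CC"))
    ck <- add_probe(ck, paste0(tag, "_cv1"), "transmural",
                    paste0("t_", tn, "_CV1"))
    ck <- add_probe(ck, paste0(tag, "_cv2"), "transmural",
                    paste0("t_", tn, "_CV2"))
    ck <- add_probe(ck, paste0("pa_", terr), "pressure",
                    paste0("pa_", tn))
  }
  sys <- assemble(ck, solver)
  run <- integrate_circuit(sys, solver, c(0, duration),
                           init = default_init(sys))
  ppg <- stats::setNames(
    lapply(territories, function(terr) {
      ppg_signal(run, paste0("ppg_", terr), probe = ppg_probe)
    }), territories)
  structure(list(probes = run$probes, ppg = ppg,
                 config = list(age = age, ratio_cd = ratio_cd,
                               territories = territories,
                               duration = duration,
                               measure_after = measure_after,
                               heart_period = heart_period,
                               stroke_volume = stroke_volume,
                               systolic_fraction = systolic_fraction,
                               parameter_set = pset$name,
                               ppg_probe = ppg_probe),
                 diagnostics = run$diagnostics),
            class = "cerebral_sim")
}

#' Extract waveform features from a simulation
#'
#' @param sim a `cerebral_sim` object.
#' @param ... unused.
#' @return For `features()`: a data frame with one row per territory (the
#'   eight PPG waveform features of the first measured cardiac cycle) plus
#'   an `icp` row summarising the ICP cycle.
#' @export
features <- function(sim, ...) UseMethod("features")

#' @rdname features
#' @export
features.cerebral_sim <- function(sim, ...) {
  cfg <- sim$config
  t0 <- first_cycle_start(cfg$measure_after, cfg$heart_period)
  rows <- lapply(cfg$territories, function(terr) {
    cf <- extract_cycle(sim$ppg[[terr]], t0, cfg$heart_period)
    cbind(data.frame(age = cfg$age, ratio_cd = cfg$ratio_cd,
                     territory = terr, signal = "ppg",
                     stringsAsFactors = FALSE),
          as.data.frame(cf))
  })
  icp_mmHg <- ts_to_mmHg(sim$probes$icp)
  icp_cf <- extract_cycle(icp_mmHg, t0, cfg$heart_period)
  rows[[length(rows) + 1L]] <-
    cbind(data.frame(age = cfg$age, ratio_cd = cfg$ratio_cd,
                     territory = "intracranial", signal = "icp",
                     stringsAsFactors = FALSE),
          as.data.frame(icp_cf))
  do.call(rbind, rows)
}

# measurement cycles start exactly at measure_after (phase-locked to the
# inflow, which starts ejecting at t = 0)
first_cycle_start <- function(measure_after, T) {
  ceiling(measure_after / T - 1e-9) * T
}

#' @export
print.cerebral_sim <- function(x, ...) {
  cfg <- x$config
  cat("Coupled ICP/PPG simulation\n")
  cat(sprintf("  age %g y, capacitance reduction %.0f%%, parameter set %s\n",
              cfg$age, 100 * (1 - cfg$ratio_cd), cfg$parameter_set))
  cat(sprintf("  %g s at T = %g s; territories: %s\n", cfg$duration,
              cfg$heart_period, paste(cfg$territories, collapse = ", ")))
  invisible(x)
}

#' @export
summary.cerebral_sim <- function(object, ...) {
  cfg <- object$config
  t0 <- first_cycle_start(cfg$measure_after, cfg$heart_period)
  sel <- object$probes$icp$t >= t0 - 1e-9 &
    object$probes$icp$t < t0 + cfg$heart_period
  icp <- Pa_to_mmHg(object$probes$icp$v[sel])
  root <- Pa_to_mmHg(object$probes$p_root$v[sel])
  out <- list(config = cfg,
              icp_mmHg = c(min = min(icp), mean = mean(icp), max = max(icp)),
              aortic_root_mmHg = c(min = min(root), mean = mean(root),
                                   max = max(root)),
              features = features(object))
  class(out) <- "summary.cerebral_sim"
  out
}

#' @export
print.summary.cerebral_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario: age %g y, %.0f%% intracranial capacitance reduction\n",
              cfg$age, 100 * (1 - cfg$ratio_cd)))
  cat(sprintf("Measured cycle: first cardiac cycle after %g s\n",
              cfg$measure_after))
  cat(sprintf("ICP [mmHg]: min %.2f  mean %.2f  max %.2f\n",
              x$icp_mmHg["min"], x$icp_mmHg["mean"], x$icp_mmHg["max"]))
  cat(sprintf("Aortic root [mmHg]: min %.1f  mean %.1f  max %.1f\n",
              x$aortic_root_mmHg["min"], x$aortic_root_mmHg["mean"],
              x$aortic_root_mmHg["max"]))
  cat("PPG waveform features:\n")
  f <- x$features[x$features$signal == "ppg",
                  c("territory", "maximum", "minimum", "mean", "amplitude",
                    "min_to_max_time", "PI", "RI", "MMR")]
  print(format(f, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.cerebral_sim <- function(x, window = NULL, ...) {
  cfg <- x$config
  if (is.null(window)) {
    window <- c(cfg$measure_after, min(cfg$measure_after + 4, cfg$duration))
  }
  op <- graphics::par(mfrow = c(length(x$ppg) + 1L, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  sel <- x$probes$icp$t >= window[1] & x$probes$icp$t <= window[2]
  graphics::plot(x$probes$icp$t[sel], Pa_to_mmHg(x$probes$icp$v[sel]),
                 type = "l", xlab = "", ylab = "ICP [mmHg]")
  for (terr in names(x$ppg)) {
    graphics::plot(x$ppg[[terr]]$t[sel], x$ppg[[terr]]$v[sel], type = "l",
                   xlab = "", ylab = paste0("PPG ", terr, " [Pa]"))
  }
  invisible(x)
}
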
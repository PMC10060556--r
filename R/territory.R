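#' Per-territory microcirculation model
#'
#' Each simulated perfusion territory (ACA/MCA/PCA) replaces the lumped
#' distal branch of its cerebral outlet terminal with an explicit
#' arteriole-capillary-venule chain: equally divided arteriole resistances
#' RA1/RA2, capillary resistance RC, equally divided venule resistances
#' RV2/RV1, with the capillary capacitance CC and the equally divided
#' venular capacitances CV1/CV2 attached at the RC/RV2, RV2/RV1 and
#' RV1/outlet junctions.  An arteriovenous-anastomosis resistance RAVA
#' bridges the arteriole midpoint to the venule midpoint.  The chain
#' resistances (excluding RAVA) sum to the terminal's distal resistance and
#' the three capacitances sum to the terminal's capacitance, partitioned
#' according to [microcirculation_ratios()].  All capacitors are referenced
#' to the ICP node, so the simulated PPG — the summed transmural pressure of
#' the capacitance elements — reflects microvascular blood volume relative
#' to the intracranial pressure.
#'
#' `build_territory()` returns the chain as a standalone circuit driven by a
#' constant inlet pressure, with the venous end at the 5 mmHg venous source
#' and a pinned ICP reference, convenient for DC analysis; inside the full
#' model the chain is attached by [couple()], which pins the venous end to
#' the ICP node instead.
#'
#' @param territory one of `"ACA-L"`, `"MCA-L"`, `"PCA-L"` (right-side
#'   territories are accepted but are not exercised by the shipped scenario
#'   grid).
#' @param pset an [artery_parameter_set()].
#' @param ratios a [microcirculation_ratios()] list.
#' @param inlet_pressure constant inlet (arterial) pressure, mmHg.
#' @param icp_pressure pinned ICP reference pressure, mmHg.
#' @return A [circuit()] with probes `ppg_cc`, `ppg_cv1`, `ppg_cv2`
#'   (capacitor transmural pressures) and `prearteriole` (node pressure).
#' @export
build_territory <- function(territory, pset = artery_parameter_set("scenario1"),
                            ratios = microcirculation_ratios(),
                            inlet_pressure = 90, icp_pressure = 10) {
  row <- terminal_row(pset, territory)
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "venous")
  ck <- add_pressure_source(ck, "src_venous", "venous", mmHg_to_Pa(5))
  ck <- add_node(ck, "icp_ref")
  ck <- add_pressure_source(ck, "src_icp", "icp_ref",
                            mmHg_to_Pa(icp_pressure))
  ck <- add_node(ck, "inlet")
  ck <- add_pressure_source(ck, "src_inlet", "inlet",
                            mmHg_to_Pa(inlet_pressure))
  ck <- add_node(ck, "pa", "prearteriole")
  ck <- add_resistor(ck, "R_p", "inlet", "pa", row$Rp_SI)
  ck <- add_territory_chain(ck, prefix = "t", pa = "pa", end = "venous",
                            Rd = row$Rd_SI, C = row$C_SI, ratios = ratios,
                            ext_ref = "icp_ref", new_end_node = FALSE)
  ck <- add_probe(ck, "ppg_cc", "transmural", "t_CC")
  ck <- add_probe(ck, "ppg_cv1", "transmural", "t_CV1")
  ck <- add_probe(ck, "ppg_cv2", "transmural", "t_CV2")
  ck <- add_probe(ck, "prearteriole", "pressure", "pa")
  ck
}

# shared chain builder: pa -RA1- ma -RA2- n1 -RC- n2 -RV2- n3 -RV1- end,
# CC at n2, CV1 at n3, CV2 at the end junction, RAVA from ma to n3
add_territory_chain <- function(ck, prefix, pa, end, Rd, C, ratios, ext_ref,
                                new_end_node = TRUE) {
  ra <- ratios$r_arteriole * Rd / 2
  rc <- ratios$r_capillary * Rd
  rv <- ratios$r_venule * Rd / 2
  cc <- ratios$c_capillary_frac * C
  cv <- (1 - ratios$c_capillary_frac) * C / 2
  ma <- paste0(prefix, "_ma"); n1 <- paste0(prefix, "_n1")
  n2 <- paste0(prefix, "_n2"); n3 <- paste0(prefix, "_n3")
  for (n in c(ma, n1, n2, n3)) ck <- add_node(ck, n)
  if (new_end_node) ck <- add_node(ck, end)
  ck <- add_resistor(ck, paste0(prefix, "_RA1"), pa, ma, ra)
  ck <- add_resistor(ck, paste0(prefix, "_RA2"), ma, n1, ra)
  ck <- add_resistor(ck, paste0(prefix, "_RC"), n1, n2, rc)
  ck <- add_resistor(ck, paste0(prefix, "_RV2"), n2, n3, rv)
  ck <- add_resistor(ck, paste0(prefix, "_RV1"), n3, end, rv)
  ck <- add_resistor(ck, paste0(prefix, "_RAVA"), ma, n3,
                     ratios$rava_multiplier * 2 * ra)
  # true two-terminal capacitors into the ICP reference: the displaced
  # microvascular volume loads the craniospinal compartment, so the bed both
  # filters the pulse and contributes to the ICP pulsation
  ck <- add_capacitor(ck, paste0(prefix, "_CC"), n2, neg = ext_ref,
                      value = cc)
  ck <- add_capacitor(ck, paste0(prefix, "_CV1"), n3, neg = ext_ref,
                      value = cv)
  ck <- add_capacitor(ck, paste0(prefix, "_CV2"), end, neg = ext_ref,
                      value = cv)
  ck
}

#' Extract the simulated PPG signal of a territory
#'
#' The simulated PPG is the sum of the transmural pressures across the
#' territory's three capacitance elements (capillary CC plus venular
#' CV1/CV2), in Pa: a volume-proportional analogue of the optical PPG
#' signal.  A capillary-only variant is available via `probe`.
#'
#' @param run a `circuit_run` containing the territory's capacitor probes
#'   (named `<tag>_cc`, `<tag>_cv1`, `<tag>_cv2`).
#' @param tag probe-name prefix, e.g. `"ppg"` for [build_territory()] runs
#'   or `"ppg_MCA-L"` inside [simulate_cerebral()] results.
#' @param probe `"sum"` (default) or `"capillary"`.
#' @return A [timeseries()] in Pa.
#' @export
ppg_signal <- function(run, tag = "ppg", probe = c("sum", "capillary")) {
  probe <- match.arg(probe)
  nm <- paste0(tag, c("_cc", "_cv1", "_cv2"))
  if (!all(nm %in% names(run$probes))) {
    stop("run does not contain the capacitor probes ",
         paste(setdiff(nm, names(run$probes)), collapse = ", "),
         call. = FALSE)
  }
  cc <- run$probes[[nm[1]]]
  v <- if (probe == "capillary") cc$v else {
    cc$v + run$probes[[nm[2]]]$v + run$probes[[nm[3]]]$v
  }
  timeseries(cc$t, v, "Pa")
}
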
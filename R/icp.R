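#' Build the intracranial pressure circuit
#'
#' The ICP compartment is an electrical analog of intracranial
#' hydrodynamics: an arterial inlet feeds proximal (R1-1, R1-2, Ci-1) and
#' distal (R2-1, R2-2, Ci-2) arterial cerebrovascular beds down to a
#' capillary node; cerebrospinal fluid forms through `Rf` behind a one-way
#' valve from the capillary node into the ICP node and drains through `Ro`
#' behind a second one-way valve into the venous sinus; blood returns
#' through the venous chain Rpv-Rdv-Rve (compliances Cvi, Cue) to the
#' central venous pressure `Pcv`.  The ICP node itself carries the piecewise
#' pressure-dependent craniospinal capacitance of
#' [intracranial_capacitance()], scaled by the capacitance-reduction ratio.
#' The arterial-bed and intracranial venous compliances are transmural with
#' respect to ICP (two-terminal capacitors to the ICP node), so arterial
#' pulsation displaces volume into the craniospinal compartment.
#'
#' `build_icp_circuit()` returns the fragment as a standalone circuit driven
#' by a constant arterial pressure source, which is convenient for studying
#' its DC fixed point; inside the full model the same fragment is attached
#' to the artery network by [couple()].
#'
#' @param params an [icp_parameters()] list.
#' @param ratio_cd capacitance-reduction ratio in (0, 1].
#' @param arterial_pressure constant inlet pressure, mmHg (standalone only).
#' @return A [circuit()] with probes `icp`, `q_formation`, `q_outflow`.
#' @export
build_icp_circuit <- function(params = icp_parameters(), ratio_cd = 1,
                              arterial_pressure = 85) {
  stopifnot(inherits(params, "icp_parameters"))
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "icp_a_in", "arterial inlet")
  ck <- add_pressure_source(ck, "src_icp_a", "icp_a_in",
                            mmHg_to_Pa(arterial_pressure))
  ck <- add_icp_fragment(ck, params, ratio_cd)
  ck <- add_probe(ck, "icp", "pressure", "icp")
  ck <- add_probe(ck, "q_formation", "flow", "D_csf_form")
  ck <- add_probe(ck, "q_outflow", "flow", "D_csf_out")
  ck
}

# attach the ICP fragment to an existing circuit; expects node icp_a_in
add_icp_fragment <- function(ck, p, ratio_cd) {
  for (n in c("icp_pa1", "icp_pa2", "icp_pa3", "icp_cap", "icp", "icp_ven",
              "icp_ue", "icp_pcv")) {
    ck <- add_node(ck, n)
  }
  ck <- add_pressure_source(ck, "src_pcv", "icp_pcv", p$Pcv)
  # arterial cerebrovascular beds
  ck <- add_resistor(ck, "R1_1", "icp_a_in", "icp_pa1", p$R1_1)
  ck <- add_resistor(ck, "R1_2", "icp_pa1", "icp_pa2", p$R1_2)
  ck <- add_resistor(ck, "R2_1", "icp_pa2", "icp_pa3", p$R2_1)
  ck <- add_resistor(ck, "R2_2", "icp_pa3", "icp_cap", p$R2_2)
  ck <- add_capacitor(ck, "Ci_1", "icp_pa1", neg = "icp", value = p$Ci_1)
  ck <- add_capacitor(ck, "Ci_2", "icp_pa3", neg = "icp", value = p$Ci_2)
  # craniospinal compartment
  ck <- add_capacitor(ck, "Cic", "icp", law = cap_law_icp(ratio_cd))
  # CSF formation and outflow through one-way valves
  ck <- add_diode(ck, "D_csf_form", "icp_cap", "icp", series_r = p$Rf)
  ck <- add_diode(ck, "D_csf_out", "icp", "icp_ven", series_r = p$Ro)
  # venous return
  ck <- add_resistor(ck, "Rpv", "icp_cap", "icp_ven", p$Rpv)
  ck <- add_resistor(ck, "Rdv", "icp_ven", "icp_ue", p$Rdv)
  ck <- add_resistor(ck, "Rve", "icp_ue", "icp_pcv", p$Rve)
  ck <- add_capacitor(ck, "Cvi", "icp_ven", neg = "icp", value = p$Cvi)
  ck <- add_capacitor(ck, "Cue", "icp_ue", value = p$Cue)
  ck
}

#' Couple the artery network, ICP circuit and territory models
#'
#' Produces the monolithic model integrated by [simulate_cerebral()]:
#' \enumerate{
#' \item the ICP circuit's arterial inlet is driven from the distal internal
#'   carotid (left/right) and basilar nodes through equal coupling
#'   resistances (the three intracranial supply trunks);
#' \item every cerebral outlet terminal's distal reference source is replaced
#'   by a tracking source pinned to the instantaneous ICP node pressure, so
#'   rising ICP raises the microvascular outlet pressure and throttles
#'   cerebral perfusion;
#' \item for each requested perfusion territory the terminal's lumped distal
#'   branch is replaced by an arteriole-capillary-venule chain
#'   ([build_territory()] semantics) whose capacitors are referenced to the
#'   ICP node and whose venous end is likewise pinned to ICP.
#' }
#'
#' @param network a circuit from [build_network()].
#' @param params an [icp_parameters()] list.
#' @param ratio_cd intracranial capacitance-reduction ratio in (0, 1].
#' @param pset the [artery_parameter_set()] used to build `network`.
#' @param ratios a [microcirculation_ratios()] list.
#' @param territories cerebral territories receiving an explicit
#'   microcirculation model (default: the three left-side territories).
#' @return The coupled [circuit()].
#' @export
couple <- function(network, params = icp_parameters(), ratio_cd = 1,
                   pset = artery_parameter_set("scenario1"),
                   ratios = microcirculation_ratios(),
                   territories = c("ACA-L", "MCA-L", "PCA-L")) {
  stopifnot(inherits(network, "circuit"))
  bad <- setdiff(territories, cerebral_territories())
  if (length(bad)) {
    stop("unknown cerebral territories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ck <- network
  ck <- add_node(ck, "icp_a_in", "ICP-model arterial inlet")
  for (trunk in c("ica_e_l", "ica_e_r", "bas_e")) {
    if (!trunk %in% ck$nodes$id) {
      stop("coupling requires network node ", trunk, call. = FALSE)
    }
    ck <- add_resistor(ck, paste0("R_couple_", trunk), trunk, "icp_a_in",
                       params$R_couple)
  }
  ck <- add_icp_fragment(ck, params, ratio_cd)

  # cerebral outlet references follow the ICP node
  cer <- pset$terminals[pset$terminals$reference == "icp_coupled", ]
  for (tn in cer$name) {
    ck <- remove_element(ck, paste0("src_ref_", tn))
    ck <- add_tracking_source(ck, paste0("trk_ref_", tn),
                              paste0("ref_", tn), "icp")
  }
  # explicit microcirculation chains for the requested territories
  for (terr in territories) {
    row <- terminal_row(pset, terr)
    ck <- remove_element(ck, paste0("C_t_", row$name))
    ck <- remove_element(ck, paste0("R_d_", row$name))
    ck <- add_territory_chain(ck, prefix = paste0("t_", row$name),
                              pa = paste0("pa_", row$name),
                              end = paste0("ref_", row$name),
                              Rd = row$Rd_SI, C = row$C_SI, ratios = ratios,
                              ext_ref = "icp", new_end_node = FALSE)
  }
  attr(ck, "ratio_cd") <- ratio_cd
  attr(ck, "territories") <- territories
  ck
}

remove_element <- function(ckt, id) {
  ids <- vapply(ckt$elements, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) stop("no such element to remove: ", id, call. = FALSE)
  ckt$elements[[i]] <- NULL
  ckt
}
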
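#' Build the cardiocerebral artery network
#'
#' Constructs the 33-segment arterial circuit: 22 intermediate segments
#' (ascending aorta, two aortic-arch segments, brachiocephalic, common
#' carotid, subclavian, vertebral and two-segment internal carotid arteries,
#' basilar artery, and the communicating arteries and first ACA/PCA segments
#' closing the Circle of Willis) plus 11 outlet terminals (thoracic aorta,
#' brachial, external carotid, and the six cerebral territories).  Each
#' intermediate segment is a three-element Windkessel: a series
#' resistance-inertance branch with the wall compliance split equally between
#' its end nodes.  The three aortic segments share the age-dependent
#' nonlinear aortic capacitance law (distributed proportionally to segment
#' length) and the common carotids use the age-dependent exponential law;
#' every other element is age-independent.  Outlets are three-element
#' Windkessel terminals draining to a 5 mmHg venous source; cerebral outlet
#' reference nodes are created here (pinned at 5 mmHg until [couple()]
#' replaces them with the ICP node pressure).  The cardiac inflow enters the
#' aortic root as a flow source.
#'
#' @param age subject age in years (20--70).
#' @param pset an [artery_parameter_set()].
#' @param heart_period heart period T, s.
#' @param stroke_volume stroke volume, m^3.
#' @param systolic_fraction systolic fraction of the heart period.
#' @return A [circuit()] containing the full network.
#' @export
build_network <- function(age, pset = artery_parameter_set("scenario1"),
                          heart_period = 0.8, stroke_volume = 85e-6,
                          systolic_fraction = 0.35) {
  check_age(age)
  stopifnot(inherits(pset, "parameter_set"))
  seg <- pset$segments
  ter <- pset$terminals

  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "venous", "systemic venous pool")
  ck <- add_pressure_source(ck, "src_venous", "venous", mmHg_to_Pa(5))

  for (nid in unique(c(seg$proximal_node, seg$distal_node))) {
    ck <- add_node(ck, nid)
  }

  # series resistance-inertance branch per segment
  for (i in seq_len(nrow(seg))) {
    ck <- add_inductor(ck, paste0("RL_", seg$name[i]),
                       seg$proximal_node[i], seg$distal_node[i],
                       value = seg$L_SI[i], series_r = seg$R_SI[i])
  }

  # wall compliance: half at each end node; aorta/CCA segments use their laws
  l_aorta_total <- sum(seg$length_cm[seg$law == "aorta"]) / 100
  for (i in seq_len(nrow(seg))) {
    for (end in c("p", "d")) {
      node <- if (end == "p") seg$proximal_node[i] else seg$distal_node[i]
      id <- paste0("C_", seg$name[i], "_", end)
      ck <- switch(seg$law[i],
        aorta = add_capacitor(ck, id, node, law = cap_law_aorta(
          age, L_aorta = l_aorta_total,
          scale = (seg$length_cm[i] / 100) / l_aorta_total / 2)),
        cca = add_capacitor(ck, id, node, law = cap_law_cca(age, scale = 0.5)),
        add_capacitor(ck, id, node, value = seg$C_SI[i] / 2))
    }
  }

  # outlet terminals: Rp -> prearteriole node (C) -> Rd -> reference
  for (i in seq_len(nrow(ter))) {
    tn <- ter$name[i]
    pa <- paste0("pa_", tn)
    ck <- add_node(ck, pa, paste0("prearteriole ", ter$territory[i]))
    ck <- add_resistor(ck, paste0("R_p_", tn), ter$artery_node[i], pa,
                       ter$Rp_SI[i])
    ck <- add_capacitor(ck, paste0("C_t_", tn), pa, value = ter$C_SI[i])
    if (ter$reference[i] == "venous_source") {
      ref <- "venous"
    } else {
      ref <- paste0("ref_", tn)
      ck <- add_node(ck, ref, paste0("microvascular outlet ", tn))
      ck <- add_pressure_source(ck, paste0("src_ref_", tn), ref,
                                mmHg_to_Pa(5))
    }
    ck <- add_resistor(ck, paste0("R_d_", tn), pa, ref, ter$Rd_SI[i])
  }

  ck <- add_flow_source(ck, "Q_heart", "root",
                        value = inflow_closure(heart_period, stroke_volume,
                                               systolic_fraction))
  attr(ck, "age") <- age
  attr(ck, "pset_name") <- pset$name
  attr(ck, "heart_period") <- heart_period
  ck
}

inflow_closure <- function(T, sv, sf) {
  force(T); force(sv); force(sf)
  f <- function(t) cardiac_inflow(t, T = T, stroke_volume = sv,
                                  systolic_fraction = sf)
  # marks the closure as a half-sine source the compiled evaluator understands
  attr(f, "halfsine") <- c(T = T, sv = sv, sf = sf)
  f
}

terminal_row <- function(pset, territory) {
  i <- match(territory, pset$terminals$territory)
  if (is.na(i)) stop("unknown territory: ", territory, call. = FALSE)
  pset$terminals[i, ]
}

# default initial node pressures: arteries at 80 mmHg, the arteriolar /
# capillary beds on a falling gradient towards the venous side, venous and
# ICP nodes at 5 mmHg, inductor flows zero; starting the beds near their
# working pressures keeps the initialization transient from displacing
# spurious volume through the transmural compliances into the craniospinal
# compartment.  The first 10 s of every run are discarded in any case.
default_init <- function(sys) {
  ids <- sys$free_ids
  p0 <- rep(80, length(ids))
  p0[ids == "icp_pa1"] <- 65
  p0[ids == "icp_pa2"] <- 55
  p0[ids == "icp_pa3"] <- 45
  p0[ids == "icp_cap"] <- 30
  p0[grepl("_ma$", ids)] <- 55
  p0[grepl("_n1$", ids)] <- 40
  p0[grepl("_n2$", ids)] <- 25
  p0[grepl("_n3$", ids)] <- 12
  p0[ids %in% c("icp", "icp_ven", "icp_ue")] <- 5
  stats::setNames(mmHg_to_Pa(p0), ids)
}
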
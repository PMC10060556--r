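#' Versioned parameter tables
#'
#' The anatomical and circuit parameters of the models are shipped as plain
#' CSV tables under `inst/extdata` and loaded by these accessors.  Two
#' parameter sets are provided: `"scenario1"` (the default, calibrated set)
#' and `"scenario2"` (an alternative source anatomy with the same topology,
#' used to explore the sensitivity of the simulated signals to individual
#' vascular anatomy).  Segment Windkessel elements are derived from vessel
#' anatomy by Poiseuille resistance \eqn{R = 8 \mu l / (\pi r^4)}, blood
#' inertance \eqn{L = \rho l / (\pi r^2)} and thin-walled elastic compliance
#' \eqn{C = 3 \pi r^3 l / (2 E h)} with blood viscosity 4 mPa s and density
#' 1050 kg/m^3.  Every row carries a provenance note; the tables are
#' calibratable configuration, not ground truth.
#'
#' @param name parameter-set name, `"scenario1"` or `"scenario2"`.
#' @return `artery_parameter_set()` returns a list of class
#'   `parameter_set` with `segments` and `terminals` data frames (SI columns
#'   added) and the set name.
#' @export
artery_parameter_set <- function(name = c("scenario1", "scenario2")) {
  name <- match.arg(name)
  seg <- utils::read.csv(pkg_extdata(paste0("segments_", name, ".csv")),
                         stringsAsFactors = FALSE)
  ter <- utils::read.csv(pkg_extdata(paste0("terminals_", name, ".csv")),
                         stringsAsFactors = FALSE)
  mu <- 4e-3; rho <- 1050
  l <- seg$length_cm / 100; r <- seg$radius_cm / 100
  E <- seg$E_MPa * 1e6; h <- seg$h_rel * r
  seg$R_SI <- 8 * mu * l / (pi * r^4)
  seg$L_SI <- rho * l / (pi * r^2)
  seg$C_SI <- 3 * pi * r^3 * l / (2 * E * h)
  ter$R_total_SI <- mmHg_s_per_ml_to_SI(ter$R_total_mmHg_s_ml)
  ter$Rp_SI <- ter$R_total_SI * ter$rp_frac
  ter$Rd_SI <- ter$R_total_SI * (1 - ter$rp_frac)
  ter$C_SI <- ter$tau_s / ter$R_total_SI
  ps <- list(name = name, segments = seg, terminals = ter)
  class(ps) <- "parameter_set"
  validate_parameter_set(ps)
  ps
}

validate_parameter_set <- function(ps) {
  seg <- ps$segments
  needed <- c("asc_aorta", "aortic_arch_1", "aortic_arch_2",
              "brachiocephalic", "cca_l", "cca_r", "subclavian_l",
              "subclavian_r", "vertebral_l", "vertebral_r", "ica_1_l",
              "ica_1_r", "ica_2_l", "ica_2_r", "basilar", "pcoa_l",
              "pcoa_r", "acoa", "aca_1_l", "aca_1_r", "pca_1_l", "pca_1_r")
  miss <- setdiff(needed, seg$name)
  if (length(miss)) {
    stop("parameter set is missing segments: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(seg$name)) {
    stop("duplicate segment rows: ",
         paste(seg$name[duplicated(seg$name)], collapse = ", "),
         call. = FALSE)
  }
  terr <- c("ACA-L", "ACA-R", "MCA-L", "MCA-R", "PCA-L", "PCA-R", "ECA-L",
            "ECA-R", "brachial-L", "brachial-R", "thoracic_aorta")
  miss <- setdiff(terr, ps$terminals$territory)
  if (length(miss)) {
    stop("parameter set is missing outlet territories: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cer <- cerebral_territories()
  bad <- ps$terminals$territory %in% cer &
    ps$terminals$reference != "icp_coupled"
  if (any(bad)) stop("cerebral terminals must be icp_coupled", call. = FALSE)
  bad <- !(ps$terminals$territory %in% cer) &
    ps$terminals$reference != "venous_source"
  if (any(bad)) {
    stop("extracranial terminals must reference the venous source",
         call. = FALSE)
  }
  if (nrow(seg) + nrow(ps$terminals) != 33L) {
    stop("expected 33 artery segments in total (22 intermediate + 11 outlet)",
         call. = FALSE)
  }
  invisible(ps)
}

cerebral_territories <- function() {
  c("ACA-L", "ACA-R", "MCA-L", "MCA-R", "PCA-L", "PCA-R")
}

#' @rdname artery_parameter_set
#' @param file optional path to an ICP parameter CSV; default is the shipped
#'   calibrated table.
#' @return `icp_parameters()` returns a named list of class `icp_parameters`
#'   with all resistances in Pa*s/m^3, compliances in m^3/Pa and `Pcv` in Pa.
#' @export
icp_parameters <- function(file = NULL) {
  if (is.null(file)) file <- pkg_extdata("icp_parameters.csv")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  p <- stats::setNames(as.list(tab$value), tab$name)
  unit <- stats::setNames(tab$unit, tab$name)
  for (nm in names(p)) {
    p[[nm]] <- switch(unit[[nm]],
      mmHg_s_ml = mmHg_s_per_ml_to_SI(p[[nm]]),
      ml_mmHg = ml_per_mmHg_to_SI(p[[nm]]),
      mmHg = mmHg_to_Pa(p[[nm]]),
      stop("unknown unit in ICP parameter table: ", unit[[nm]]))
  }
  needed <- c("R_couple", "R1_1", "R1_2", "Ci_1", "R2_1", "R2_2", "Ci_2",
              "Cvi", "Rpv", "Rdv", "Rve", "Cue", "Rf", "Ro", "Pcv")
  miss <- setdiff(needed, names(p))
  if (length(miss)) {
    stop("ICP parameter table missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(p) <= 0)) {
    stop("all ICP circuit parameters must be positive", call. = FALSE)
  }
  structure(p, class = "icp_parameters")
}

#' @rdname artery_parameter_set
#' @return `microcirculation_ratios()` returns a named list with the
#'   arteriole/capillary/venule resistance fractions (summing to 1), the
#'   capillary share of the territory capacitance and the anastomosis
#'   resistance expressed as a multiple of the total arteriole resistance.
#' @export
microcirculation_ratios <- function(file = NULL) {
  if (is.null(file)) file <- pkg_extdata("microcirculation_ratios.csv")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  p <- stats::setNames(as.list(tab$value), tab$key)
  needed <- c("r_arteriole", "r_capillary", "r_venule", "c_capillary_frac",
              "rava_multiplier")
  miss <- setdiff(needed, names(p))
  if (length(miss)) {
    stop("ratio table missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- p$r_arteriole + p$r_capillary + p$r_venule
  if (abs(s - 1) > 1e-6) {
    stop("arteriole/capillary/venule resistance fractions must sum to 1",
         call. = FALSE)
  }
  if (p$c_capillary_frac <= 0 || p$c_capillary_frac >= 1) {
    stop("c_capillary_frac must be in (0, 1)", call. = FALSE)
  }
  structure(p, class = "microcirculation_ratios")
}

pkg_extdata <- function(f) {
  path <- system.file("extdata", f, package = "icpwave")
  if (!nzchar(path)) stop("missing packaged data file: ", f, call. = FALSE)
  path
}
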
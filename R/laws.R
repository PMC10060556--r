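#' Age-dependent nonlinear aortic capacitance
#'
#' Pressure-dependent Windkessel capacitance of the aorta.  The aortic wall
#' compliance peaks at an age-dependent reference pressure `P0` and falls off
#' with the square of the normalised distance from it:
#'
#' \deqn{C(P) = \frac{A_{max} L}{\pi P_1 \left[1 + \left(\frac{P - P_0}{P_1}\right)^2\right]}}
#'
#' with \eqn{P_0 = 76 - 0.98\,\mathrm{age}} mmHg and
#' \eqn{P_1 = 57 - 0.44\,\mathrm{age}} mmHg, both valid for ages 20--70 years.
#' `Amax` is the maximal aortic cross-sectional area (5.8 cm^2 for male
#' adults) and `L` the aortic length.  Older subjects therefore have a lower
#' and narrower compliance curve: at a working pressure of 100 mmHg the aorta
#' stiffens monotonically with age.
#'
#' @param P local blood pressure, mmHg (vectorised).
#' @param age age in years, in \[20, 70\].
#' @param L_aorta aortic length, m.
#' @param Amax maximal aortic cross-sectional area, m^2.
#' @return Capacitance in m^3/Pa (SI).
#' @seealso [cca_capacitance()], [intracranial_capacitance()]
#' @export
#' @examples
#' aorta_capacitance(100, age = 40, L_aorta = 0.099)
aorta_capacitance <- function(P, age, L_aorta, Amax = 5.8e-4) {
  check_age(age)
  stopifnot(L_aorta > 0, Amax > 0)
  P0 <- 76 - 0.98 * age
  P1 <- 57 - 0.44 * age
  c_per_mmHg <- Amax * L_aorta / (pi * P1 * (1 + ((P - P0) / P1)^2))
  c_per_mmHg / 133.322  # per-mmHg -> per-Pa
}

#' Age-dependent exponential common-carotid capacitance
#'
#' Compliance of the common carotid artery (CCA), exponentially decreasing
#' with transmural blood pressure and linearly decreasing with age:
#'
#' \deqn{C(P) = C_{ref}\, e^{-b (P - P_{ref})}\, \left[1.3 - 0.012\,(\mathrm{age}-20)\right]}
#'
#' where \eqn{C_{ref} = a\, e^{-b P_{ref}}} with `a` = 3.14 ml/mmHg,
#' `b` = 0.018 1/mmHg and `Pref` = 100 mmHg (the conventional mean arterial
#' pressure of healthy adults).  The bracketed age factor spans 1.3 at age 20
#' down to 0.7 at age 70, so the carotid buffers the pulse wave progressively
#' less in older subjects.
#'
#' @param P transient CCA blood pressure, mmHg (vectorised).
#' @param age age in years, in \[20, 70\].
#' @param a base compliance scale, ml/mmHg.
#' @param b pressure sensitivity, 1/mmHg.
#' @param Pref reference mean pressure, mmHg.
#' @return Capacitance in m^3/Pa (SI).
#' @export
#' @examples
#' cca_capacitance(100, age = 20)  # 1.3 * 3.14 * exp(-1.8) ml/mmHg, in SI
cca_capacitance <- function(P, age, a = 3.14, b = 0.018, Pref = 100) {
  check_age(age)
  c_ref <- a * exp(-b * Pref)                      # ml/mmHg at P = Pref
  agef <- 1.3 - 0.012 * (age - 20)
  c_ml_mmHg <- c_ref * exp(-b * (P - Pref)) * agef
  ml_per_mmHg_to_SI(c_ml_mmHg)
}

#' Piecewise pressure-dependent intracranial capacitance
#'
#' The craniospinal pressure-volume buffer.  Below the venous reference
#' pressure (5 mmHg = 666.5 Pa) the capacitance is constant; above it the
#' capacitance is inversely proportional to ICP (the classical monoexponential
#' pressure-volume relation):
#'
#' \deqn{C(\mathrm{ICP}) = \begin{cases}
#'   7.502\times 10^{-9}\; r & \mathrm{ICP} \in [0, 666.5)\ \mathrm{Pa} \\
#'   \dfrac{5\times 10^{-6}}{\mathrm{ICP}}\; r & \mathrm{ICP} \ge 666.5\ \mathrm{Pa}
#' \end{cases}}
#'
#' where `r` (`ratio_cd`) is the capacitance-reduction ratio used to emulate
#' pathological loss of intracranial compliance (1 = normal, 0.25 = 75%
#' reduction).  The two branches agree at the knot to better than 0.01%.
#'
#' @param icp intracranial pressure, Pa (vectorised; values below 0 are
#'   clamped to the constant branch).
#' @param ratio_cd capacitance-reduction ratio in (0, 1].
#' @return Capacitance in m^3/Pa.
#' @export
#' @examples
#' intracranial_capacitance(500, 1)       # constant branch
#' intracranial_capacitance(1333, 0.5)    # inverse branch
intracranial_capacitance <- function(icp, ratio_cd = 1) {
  if (!is.numeric(ratio_cd) || length(ratio_cd) != 1L ||
      ratio_cd <= 0 || ratio_cd > 1) {
    stop("'ratio_cd' must be a single value in (0, 1]", call. = FALSE)
  }
  icp <- pmax(icp, 0)
  ifelse(icp < 666.5, 7.502e-9 * ratio_cd, 5e-6 / icp * ratio_cd)
}

#' Parametric cardiac inflow waveform
#'
#' Periodic aortic inflow used as the inlet boundary condition: a half-sine
#' ejection lasting `systolic_fraction * T` followed by zero flow in diastole.
#' The one-period integral equals the stroke volume exactly.
#'
#' @param t time, s (vectorised).
#' @param T heart period, s.
#' @param stroke_volume stroke volume, m^3.
#' @param systolic_fraction fraction of the period spent ejecting.
#' @return Flow in m^3/s (non-negative, `T`-periodic).
#' @export
#' @examples
#' q <- cardiac_inflow(seq(0, 0.8, by = 1e-3))
cardiac_inflow <- function(t, T = 0.8, stroke_volume = 85e-6,
                           systolic_fraction = 0.35) {
  stopifnot(T > 0, stroke_volume > 0,
            systolic_fraction > 0, systolic_fraction < 1)
  ts <- systolic_fraction * T
  tau <- t %% T
  peak <- pi * stroke_volume / (2 * ts)   # makes the integral = stroke volume
  ifelse(tau < ts, peak * sin(pi * tau / ts), 0)
}

check_age <- function(age) {
  if (!is.numeric(age) || length(age) != 1L || age < 20 || age > 70) {
    stop("'age' must be a single value in [20, 70] years", call. = FALSE)
  }
  invisible(age)
}
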
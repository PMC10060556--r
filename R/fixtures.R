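#' Reference test circuits with analytic solutions
#'
#' Small self-contained circuits whose behaviour is known in closed form,
#' used throughout the test suite as independent oracles for the circuit
#' assembler and integrator:
#' \describe{
#' \item{`rc`}{unit RC discharge from 1 Pa; reference \eqn{P(t) = e^{-t}}.}
#' \item{`windkessel2`}{two-element Windkessel under sinusoidal inflow;
#'   reference amplitude \eqn{|Z(\omega)| = R/\sqrt{1+(\omega R C)^2}}.}
#' \item{`windkessel3`}{three-element Windkessel under constant inflow;
#'   DC reference \eqn{P = Q_0 (R_p + R_d) + P_{out}}.}
#' \item{`diode_pump`}{diode in series with a resistor between a pressure
#'   source and ground; reverse-bias leakage bound
#'   `|Q| <= g_off * |dP|`.}
#' \item{`mini_icp`}{six-element reduction of the ICP circuit (formation
#'   and outflow valves around a constant craniospinal capacitance); DC
#'   fixed point \eqn{ICP = (P_a/R_f + P_{cv}/R_o)/(1/R_f + 1/R_o)}.}
#' }
#'
#' @param kind fixture name.
#' @param file optional path; when given the circuit is also serialised
#'   with [write_circuit()].
#' @param ... fixture parameters (see the defaults in each builder).
#' @return A list with the `circuit`, a `reference` function or value, and
#'   a short `description`.
#' @export
make_fixtures <- function(kind = c("rc", "windkessel2", "windkessel3",
                                   "diode_pump", "mini_icp"),
                          file = NULL, ...) {
  kind <- match.arg(kind)
  fx <- switch(kind,
    rc = fixture_rc(...),
    windkessel2 = fixture_wk2(...),
    windkessel3 = fixture_wk3(...),
    diode_pump = fixture_diode(...),
    mini_icp = fixture_mini_icp(...))
  if (!is.null(file)) write_circuit(fx$circuit, file)
  fx
}

fixture_rc <- function(R = 1, C = 1, p0 = 1) {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "n1")
  ck <- add_resistor(ck, "R1", "n1", "ground", R)
  ck <- add_capacitor(ck, "C1", "n1", value = C)
  ck <- add_probe(ck, "p", "pressure", "n1")
  list(circuit = ck, init = c(n1 = p0),
       reference = function(t) p0 * exp(-t / (R * C)),
       description = "RC discharge, P(t) = p0 exp(-t/RC)")
}

fixture_wk2 <- function(R = 1e8, C = 1e-8, q0 = 1e-6, freq = 1.25) {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "n")
  ck <- add_flow_source(ck, "Q", "n",
                        value = local({
                          w <- 2 * pi * freq; a <- q0
                          function(t) a * sin(w * t)
                        }))
  ck <- add_resistor(ck, "Rp", "n", "ground", R)
  ck <- add_capacitor(ck, "Cp", "n", value = C)
  ck <- add_probe(ck, "p", "pressure", "n")
  w <- 2 * pi * freq
  list(circuit = ck,
       reference = q0 * R / sqrt(1 + (w * R * C)^2),
       settle = 6 * R * C,
       description = "2-element Windkessel steady-state amplitude |Z(w)| q0")
}

fixture_wk3 <- function(Rp = 1e7, C = 1e-8, Rd = 1e8, q0 = 1e-6,
                        p_out = 666.61) {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "in"); ck <- add_node(ck, "mid")
  ck <- add_node(ck, "out")
  ck <- add_flow_source(ck, "Q", "in", value = q0)
  ck <- add_resistor(ck, "Rp", "in", "mid", Rp)
  ck <- add_capacitor(ck, "Cm", "mid", value = C)
  ck <- add_resistor(ck, "Rd", "mid", "out", Rd)
  ck <- add_pressure_source(ck, "Pout", "out", p_out)
  ck <- add_probe(ck, "p_in", "pressure", "in")
  list(circuit = ck,
       reference = q0 * (Rp + Rd) + p_out,
       settle = 14 * Rd * C,
       description = "3-element Windkessel DC inlet pressure")
}

fixture_diode <- function(bias = -1, R = 1) {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "s")
  ck <- add_pressure_source(ck, "src", "s", bias)
  ck <- add_diode(ck, "D", "s", "ground", series_r = R)
  ck <- add_probe(ck, "q", "flow", "D")
  list(circuit = ck,
       reference = function(g_off) abs(bias) * g_off,
       description = "reverse-biased diode leakage bound |Q| <= g_off |dP|")
}

fixture_mini_icp <- function(Pa = mmHg_to_Pa(40), Pcv = mmHg_to_Pa(5),
                             Rf = mmHg_s_per_ml_to_SI(70),
                             Ro = mmHg_s_per_ml_to_SI(22),
                             C = 7.502e-9) {
  ck <- circuit()
  ck <- add_node(ck, "ground", ground = TRUE)
  ck <- add_node(ck, "a"); ck <- add_node(ck, "icp")
  ck <- add_node(ck, "v")
  ck <- add_pressure_source(ck, "Pa", "a", Pa)
  ck <- add_pressure_source(ck, "Pcv", "v", Pcv)
  ck <- add_diode(ck, "Df", "a", "icp", series_r = Rf)
  ck <- add_diode(ck, "Do", "icp", "v", series_r = Ro)
  ck <- add_capacitor(ck, "Cic", "icp", value = C)
  ck <- add_probe(ck, "icp", "pressure", "icp")
  list(circuit = ck,
       reference = (Pa / Rf + Pcv / Ro) / (1 / Rf + 1 / Ro),
       settle = 10 * C / (1 / Rf + 1 / Ro),
       description = "mini ICP loop DC fixed point (both valves conducting)")
}
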
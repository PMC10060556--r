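#' Unit conversion helpers
#'
#' All internal computation uses SI hydraulic units: pressure in Pa, flow in
#' m^3/s, resistance in Pa*s/m^3, inertance in Pa*s^2/m^3 and capacitance
#' (compliance) in m^3/Pa.  Millimetres of mercury and millilitres appear only
#' at input/output boundaries.  One mmHg is taken as 133.322 Pa, so that the
#' conventional 5 mmHg venous reference corresponds to the 666.5 Pa knot of the
#' intracranial capacitance law (see [intracranial_capacitance()]).
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
#' @examples
#' mmHg_to_Pa(5)      # 666.61 Pa
#' Pa_to_mmHg(666.5)  # ~5 mmHg
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

# 1 ml/mmHg in m^3/Pa
ml_per_mmHg_to_SI <- function(x) x * 1e-6 / 133.322

# 1 mmHg*s/ml in Pa*s/m^3
mmHg_s_per_ml_to_SI <- function(x) x * 133.322 / 1e-6
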
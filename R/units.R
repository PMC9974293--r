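# Unit conversions. SI everywhere internally; user-facing I/O is
# mmHg / cm / ml (1 mmHg = 133.322 Pa).

MMHG_PA <- 133.322

#' Unit conversion helpers
#'
#' Convert between the package's internal SI units and the clinical units
#' used at all user-facing interfaces (mmHg for pressure, ml/s for flow,
#' cm^2 for area, cm/s for velocity).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / MMHG_PA

# flow ml/s <-> m^3/s
ml_s_to_m3_s <- function(x) x * 1e-6
m3_s_to_ml_s <- function(x) x * 1e6

# area cm^2 <-> m^2
cm2_to_m2 <- function(x) x * 1e-4
m2_to_cm2 <- function(x) x * 1e4

# resistance mmHg*s/ml <-> Pa*s/m^3
mmHg_s_ml_to_SI <- function(x) x * MMHG_PA / 1e-6
SI_to_mmHg_s_ml <- function(x) x / MMHG_PA * 1e-6

# compliance ml/mmHg <-> m^3/Pa
ml_mmHg_to_SI <- function(x) x * 1e-6 / MMHG_PA
SI_to_ml_mmHg <- function(x) x / 1e-6 * MMHG_PA
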
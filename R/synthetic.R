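# Synthetic waveform fixtures with exactly known decompositions, used to
# validate the analysis chain without a simulation.

gauss_pulse <- function(t, t0, amp, width) amp * exp(-((t - t0) / width)^2)

#' Construct a beat with a known forward/backward decomposition
#'
#' Builds `P = P_f* + P_b*` and `Q = (P_f* - P_b*) / Zc` from Gaussian
#' forward and backward pressure pulses, so wave separation at the same
#' `Zc` must recover the constituents exactly.
#'
#' @param forward `list(amp, t0, width)` of the forward pressure pulse
#'   (Pa, s, s); `amp = 0` for none.
#' @param backward as `forward`, for the backward pulse.
#' @param Zc characteristic impedance (Pa s/m^3).
#' @param RR beat period (s).
#' @param P0 baseline pressure added to the forward component (Pa).
#' @param n_samples samples per beat.
#' @return list with the `pw_series` (`$series`) and the true components
#'   `$P_f`, `$P_b`.
#' @export
make_superposed_waves <- function(forward = list(amp = mmHg_to_Pa(20),
                                                 t0 = 0.2, width = 0.04),
                                  backward = list(amp = mmHg_to_Pa(8),
                                                  t0 = 0.5, width = 0.04),
                                  Zc = 1e7, RR = 0.8,
                                  P0 = mmHg_to_Pa(80),
                                  n_samples = 800L) {
  t <- seq(0, RR, length.out = n_samples + 1L)[-(n_samples + 1L)]
  P_f <- P0 + gauss_pulse(t, forward$t0, forward$amp, forward$width)
  P_b <- gauss_pulse(t, backward$t0, backward$amp, backward$width)
  P <- P_f + P_b
  Q <- (P_f - P_b) / Zc
  list(series = hemo_series(t, P, Q, RR = RR), P_f = P_f, P_b = P_b,
       Zc = Zc)
}

#' Construct a synthetic wave-intensity trace
#'
#' Backward wave intensity as negative Gaussian pulses at given times,
#' for testing the energy-weighted arrival time.
#'
#' @param times pulse centers (s).
#' @param widths pulse widths (s), recycled.
#' @param weights relative pulse energies, recycled.
#' @param RR beat period (s).
#' @param n_samples samples per beat.
#' @return a `pw_wi` with `WI_f = 0` and the prescribed `WI_b`.
#' @export
make_wi_fixture <- function(times, widths = 0.01, weights = 1, RR = 0.8,
                            n_samples = 2000L) {
  widths <- rep_len(widths, length(times))
  weights <- rep_len(weights, length(times))
  t <- seq(0, RR, length.out = n_samples + 1L)[-(n_samples + 1L)]
  WI_b <- numeric(length(t))
  for (k in seq_along(times))
    WI_b <- WI_b - weights[k] / (widths[k] * sqrt(pi)) *
      exp(-((t - times[k]) / widths[k])^2)
  structure(list(t = t, WI_f = numeric(length(t)), WI_b = WI_b,
                 dPdt = NULL, dUdt = NULL, rho_c = NA_real_, RR = RR,
                 vessel = NA_integer_, cell = NA_integer_),
            class = "pw_wi")
}
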
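# Root inflow source: a tabulated periodic flow waveform over one beat.

#' Build a parametric inflow waveform
#'
#' Tabulates one beat of aortic-root flow.  Ejection occupies
#' `ejection_fraction * RR` at the start of the beat; flow is zero in
#' diastole and the table is normalized so its trapezoidal integral equals
#' the requested stroke volume exactly.
#'
#' @param RR beat period (s).
#' @param SV stroke volume (m^3); `70e-6` is 70 ml.
#' @param shape `"half_sine"`, `"trapezoid"`, or `"ramp"` (fast smooth
#'   rise over 8% of the ejection, slow decay thereafter — used for
#'   echo-timing fixtures where the forward wavefront must be a single
#'   sharp compression).
#' @param ejection_fraction fraction of the beat spent in ejection.
#' @param n_samples number of table samples over the beat (first sample is
#'   repeated at `t = RR` so the table is explicitly periodic).
#' @return an object of class `pw_inflow` with fields `t`, `Q` (m^3/s),
#'   `RR`, `SV` and the generating parameters.
#' @export
inflow_waveform <- function(RR = 0.8, SV = 70e-6, shape = "half_sine",
                            ejection_fraction = 0.35, n_samples = 1000L) {
  if (!(RR > 0)) stop("RR must be > 0")
  if (!(SV > 0)) stop("SV must be > 0")
  shape <- match.arg(shape, c("half_sine", "trapezoid", "ramp"))
  stopifnot(ejection_fraction > 0, ejection_fraction < 1)
  Te <- ejection_fraction * RR
  t <- seq(0, RR, length.out = n_samples + 1L)
  Q <- switch(shape,
    half_sine = ifelse(t <= Te, sin(pi * t / Te), 0),
    trapezoid = {
      r <- 0.2 * Te
      ifelse(t <= r, t / r,
        ifelse(t <= Te - r, 1,
          ifelse(t <= Te, (Te - t) / r, 0)))
    },
    ramp = {
      r <- 0.08 * Te
      ifelse(t <= r, sin(pi * t / (2 * r))^2,
        ifelse(t <= Te, cos(pi * (t - r) / (2 * (Te - r)))^2, 0))
    })
  Q[Q < 0] <- 0
  # exact trapezoidal stroke volume
  dt <- t[2] - t[1]
  area <- sum((Q[-1] + Q[-length(Q)]) / 2) * dt
  Q <- Q * SV / area
  structure(list(t = t, Q = Q, RR = RR, SV = SV, shape = shape,
                 ejection_fraction = ejection_fraction),
            class = "pw_inflow")
}

#' Rescale an inflow source in period and stroke volume
#'
#' Used by the posture transform: the time axis is compressed by
#' `1 / f_HR` and the amplitude rescaled so the new stroke volume is
#' `f_SV` times the old one.  Works for tabulated waveforms of any shape.
#'
#' @param inflow a `pw_inflow`.
#' @param f_HR heart-rate factor (> 0); new `RR = RR / f_HR`.
#' @param f_SV stroke-volume factor (> 0).
#' @return a rescaled `pw_inflow`.
#' @export
rescale_inflow <- function(inflow, f_HR = 1, f_SV = 1) {
  stopifnot(f_HR > 0, f_SV > 0)
  out <- inflow
  out$t <- inflow$t / f_HR
  out$Q <- inflow$Q * f_SV * f_HR
  out$RR <- inflow$RR / f_HR
  out$SV <- inflow$SV * f_SV
  out
}

#' Stroke volume of a tabulated inflow
#'
#' Trapezoidal integral of the flow table over one beat.
#'
#' @param inflow a `pw_inflow`.
#' @return stroke volume (m^3).
#' @export
inflow_stroke_volume <- function(inflow) {
  trapz_uniform(inflow$t, inflow$Q)
}

# trapezoid rule on a (possibly non-uniform) grid
trapz_uniform <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' @export
print.pw_inflow <- function(x, ...) {
  cat("<pw_inflow> shape=", x$shape,
      " RR=", signif(x$RR, 4), "s",
      " SV=", signif(x$SV * 1e6, 4), "ml",
      " peak=", signif(max(x$Q) * 1e6, 5), "ml/s\n", sep = "")
  invisible(x)
}
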
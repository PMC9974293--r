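# Wave separation and wave analysis: characteristic impedance from the
# PQ-loop, wave speed from the PU-loop, forward/backward decomposition,
# reflection indices (RM, RI, AI), reflection coefficients at
# bifurcations / tapers / terminals, and input-impedance spectra.

# --- beat landmarks -------------------------------------------------------

# circular index helper
wrap_idx <- function(i, n) ((i - 1) %% n) + 1

# light running-mean smoothing of a periodic signal (landmarks only)
smooth_periodic <- function(y, w) {
  if (w < 3) return(y)
  n <- length(y)
  k <- rep(1 / w, w)
  yp <- c(y[(n - w + 1):n], y, y[1:w])
  stats::filter(yp, k, sides = 2)[(w + 1):(w + n)]
}

# locate the systolic peak and the pressure foot.  The foot is the last
# sample below (diastolic minimum + 1% of pulse pressure) on the
# diastolic minimum directly preceding the upstroke; late-diastolic
# oscillations elsewhere in the beat are ignored by walking backwards
# from the peak to the adjacent local minimum first.
beat_landmarks <- function(P) {
  n <- length(P)
  Ps <- smooth_periodic(P, max(3L, round(n / 200)))
  i_sys <- which.max(Ps)
  Pmin <- min(Ps)
  PP <- max(Ps) - Pmin
  if (PP <= 0) stop("flat pressure signal")
  # local minimum directly preceding the peak; step past shoulders that
  # sit well above the diastolic level
  i <- i_sys
  for (pass in 1:40) {
    steps <- 0
    repeat {                          # descend to the previous local min
      j <- wrap_idx(i - 1, n)
      if (Ps[j] >= Ps[i] || steps > n) break
      i <- j; steps <- steps + 1
    }
    if (Ps[i] <= Pmin + 0.10 * PP || steps > n) break
    repeat {                          # climb over the preceding bump
      j <- wrap_idx(i - 1, n)
      if (Ps[j] <= Ps[i]) break
      i <- j
    }
  }
  i_min <- i
  # spec'd refinement: last sample under min + 1% PP before the upstroke
  thr <- Ps[i_min] + 0.01 * PP
  i_foot <- i_min
  span <- circ_dist(i_min, i_sys, n)
  for (k in seq_len(span)) {
    j <- wrap_idx(i_min + k, n)
    if (Ps[j] < thr) i_foot <- j else break
  }
  list(i_sys = i_sys, i_foot = i_foot, PP = max(P) - min(P), Pmin = min(P))
}

# circular forward distance (in samples) from a to b
circ_dist <- function(a, b, n) (b - a) %% n

# --- loop-slope estimators ------------------------------------------------

loop_slope <- function(P, X, RR, what) {
  n <- length(P)
  if (max(X) - min(X) < 1e-12 * max(abs(X), 1e-300))
    stop("estimation error: flat ", what, " signal")
  lm_ <- beat_landmarks(P)
  span <- circ_dist(lm_$i_foot, lm_$i_sys, n)
  if (span < 4) stop("estimation error: upstroke too short to fit")
  frac <- 0.30
  best <- NULL
  repeat {
    m <- max(3L, ceiling(frac * span))
    idx <- wrap_idx(lm_$i_foot + 0:m, n)
    fit <- stats::lm.fit(cbind(1, X[idx]), P[idx])
    slope <- fit$coefficients[2]
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((P[idx] - mean(P[idx]))^2), 1e-300)
    if (is.null(best) || r2 > best$r2)
      best <- list(slope = slope, r2 = r2, idx = idx, frac = frac)
    if (r2 >= 0.98 || frac >= 0.60 - 1e-9) break
    frac <- frac + 0.05
  }
  flagged <- best$r2 < 0.98
  list(slope = unname(best$slope), r2 = best$r2, window = best$idx,
       flagged = flagged)
}

#' Characteristic impedance from the PQ-loop
#'
#' Least-squares slope of pressure versus flow over the early-systolic
#' window (from the pressure foot to 30% of the foot-to-peak time,
#' widened in 5% steps up to 60% until the fit reaches R^2 >= 0.98;
#' otherwise the estimate is flagged low-quality).  Early systole is
#' nearly reflection-free, so the slope estimates the local
#' characteristic impedance.
#'
#' @param series a `pw_series`.
#' @return an object of class `pw_zc` with `Zc` (Pa s/m^3), the fit
#'   window, `r2`, and a `flagged` indicator.
#' @export
estimate_zc_pq <- function(series) {
  fit <- loop_slope(series$P, series$Q, series$RR, "flow")
  structure(list(Zc = fit$slope, rho_c = NULL, c = NULL,
                 window = fit$window, r2 = fit$r2, flagged = fit$flagged),
            class = "pw_zc")
}

#' Local wave speed from the PU-loop
#'
#' As [estimate_zc_pq()] but fitting pressure against velocity; the
#' early-systolic slope is `rho c`, whence `c = slope / rho`.
#'
#' @param series a `pw_series` carrying velocity (`U`).
#' @param rho blood density (kg/m^3).
#' @return a `pw_zc` with fields `rho_c` and `c`.
#' @export
estimate_c_pu <- function(series, rho = 1050) {
  if (is.null(series$U)) stop("series carries no velocity; PU-loop unavailable")
  fit <- loop_slope(series$P, series$U, series$RR, "velocity")
  structure(list(Zc = NULL, rho_c = fit$slope, c = fit$slope / rho,
                 window = fit$window, r2 = fit$r2, flagged = fit$flagged),
            class = "pw_zc")
}

#' @export
print.pw_zc <- function(x, ...) {
  if (!is.null(x$Zc))
    cat("<pw_zc> Zc=", signif(x$Zc, 5), " Pa s/m^3", sep = "")
  if (!is.null(x$c))
    cat("<pw_zc> c=", signif(x$c, 5), " m/s", sep = "")
  cat("  R2=", signif(x$r2, 4), if (x$flagged) "  [flagged]" else "",
      "\n", sep = "")
  invisible(x)
}

# --- wave separation ------------------------------------------------------

#' Separate pressure and flow into forward and backward components
#'
#' `P_fb = (P +- Zc Q) / 2`, `Q_fb = (Q +- P / Zc) / 2`.  The formulas
#' are applied to the raw signals, mean levels included, so posture
#' shifts of mean forward/backward pressure are visible; pulse-pressure
#' based indices are unaffected by that choice.
#'
#' @param series a `pw_series`.
#' @param Zc characteristic impedance (Pa s/m^3) — a number or a
#'   `pw_zc` from [estimate_zc_pq()].
#' @return an object of class `pw_separation` with `P_f`, `P_b`, `Q_f`,
#'   `Q_b`, pulse pressures `PP_f`, `PP_b` (Pa) and mean levels.
#' @export
separate_waves <- function(series, Zc) {
  if (inherits(Zc, "pw_zc")) Zc <- Zc$Zc
  if (!(is.numeric(Zc) && Zc > 0)) stop("Zc must be a positive number")
  P <- series$P; Q <- series$Q
  P_f <- (P + Zc * Q) / 2
  P_b <- (P - Zc * Q) / 2
  Q_f <- (Q + P / Zc) / 2
  Q_b <- (Q - P / Zc) / 2
  structure(list(t = series$t, Zc = Zc,
                 P_f = P_f, P_b = P_b, Q_f = Q_f, Q_b = Q_b,
                 PP_f = max(P_f) - min(P_f),
                 PP_b = max(P_b) - min(P_b),
                 mean_P_f = mean(P_f), mean_P_b = mean(P_b),
                 vessel = series$vessel, cell = series$cell),
            class = "pw_separation")
}

#' @export
print.pw_separation <- function(x, ...) {
  cat("<pw_separation> PP_f=", signif(Pa_to_mmHg(x$PP_f), 4),
      " mmHg, PP_b=", signif(Pa_to_mmHg(x$PP_b), 4),
      " mmHg, RM=", signif(x$PP_b / x$PP_f, 3), "\n", sep = "")
  invisible(x)
}

#' Vessel-level reflection indices
#'
#' Averages forward and backward pulse pressures over a vessel's cells
#' and forms the reflection magnitude `RM = PP_b / PP_f` and reflection
#' index `RI = PP_b / (PP_f + PP_b)`.  When a reference-cell series is
#' supplied, the total pulse pressure and augmentation index are
#' computed there as well.
#'
#' @param separations list of `pw_separation`, one per cell.
#' @param reference optional `pw_series` at the vessel's reference cell.
#' @return an object of class `pw_reflection` with `PP_f`, `PP_b` (Pa),
#'   `RM`, `RI`, and (if a reference was given) `PP`, `AP`, `AI`.
#' @export
vessel_reflection_indices <- function(separations, reference = NULL) {
  if (!length(separations)) stop("need at least one cell separation")
  PP_f <- mean(vapply(separations, function(s) s$PP_f, numeric(1)))
  PP_b <- mean(vapply(separations, function(s) s$PP_b, numeric(1)))
  if (PP_f <= 0) stop("undefined reflection indices: PP_f is zero")
  RM <- PP_b / PP_f
  out <- list(PP_f = PP_f, PP_b = PP_b, RM = RM, RI = RM / (1 + RM),
              PP = NA_real_, AP = NA_real_, AI = NA_real_)
  if (!is.null(reference)) {
    out$PP <- max(reference$P) - min(reference$P)
    ai <- augmentation_index(reference)
    out$AP <- ai$AP
    out$AI <- ai$AI
  }
  structure(out, class = "pw_reflection")
}

#' @export
print.pw_reflection <- function(x, ...) {
  cat("<pw_reflection> PP_f=", signif(Pa_to_mmHg(x$PP_f), 4),
      " PP_b=", signif(Pa_to_mmHg(x$PP_b), 4),
      " mmHg  RM=", signif(x$RM, 3), " RI=", signif(x$RI, 3),
      if (!is.na(x$AI)) paste0(" AI=", signif(x$AI, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

# --- augmentation index ---------------------------------------------------

# zero-phase low-pass of a periodic beat signal
lowpass_beat <- function(y, fs, cutoff) {
  ny <- fs / 2
  if (cutoff >= ny) return(y)
  bf <- signal::butter(2, cutoff / ny)
  n <- length(y)
  # pad periodically to suppress filtfilt edge transients
  yp <- c(y, y, y)
  yf <- signal::filtfilt(bf, yp)
  yf[(n + 1):(2 * n)]
}

#' Augmentation pressure and augmentation index
#'
#' Finds the systolic inflection point from the zero-crossings of the
#' smoothed second derivative of pressure after the initial upstroke
#' acceleration phase: a shoulder before the systolic peak (a local
#' minimum of dP/dt on the upstroke) gives a positive augmentation
#' pressure `AP = P_sys - P_inflection`; a post-peak inflection (a local
#' maximum of dP/dt during the decay) gives a negative one.  `AI = AP /
#' PP`.  Waveforms without any such inflection (e.g. a single smooth
#' pulse) are returned flagged with `AI = NA` rather than silently 0.
#'
#' @param series a `pw_series`.
#' @param cutoff low-pass cutoff (Hz) applied (zero-phase) before
#'   differentiation.
#' @return list with `AP` (Pa), `AI`, `t_inflection`, `t_sys`, `flagged`.
#' @export
augmentation_index <- function(series, cutoff = 25) {
  P <- series$P
  n <- length(P)
  fs <- 1 / (series$t[2] - series$t[1])
  Ps <- lowpass_beat(P, fs, cutoff)
  lm_ <- beat_landmarks(Ps)
  # rotate so the foot is sample 1; the beat is periodic
  rot <- wrap_idx(lm_$i_foot + 0:(n - 1), n)
  Pr <- Ps[rot]
  i_sys <- which.max(Pr)
  PP <- max(P) - min(P)
  d1 <- c(diff(Pr), Pr[1] - Pr[n]) * fs
  d2 <- c(diff(d1), d1[1] - d1[n]) * fs
  d2 <- lowpass_beat(d2, fs, cutoff)
  # systolic search window: up to three upstroke durations past the peak
  i_end <- min(n - 1L, ceiling(0.6 * n), i_sys + 3L * max(i_sys, 8L))
  d2_scale <- max(abs(d2[1:i_sys]))

  sgn <- sign(d2)
  crossings <- function(from, to, dir) {
    # dir +1: - to +;  dir -1: + to -
    out <- integer(0)
    for (i in seq(from, to - 1L)) {
      if (sgn[i] == -dir && sgn[i + 1] == dir) out <- c(out, i + 1L)
    }
    out
  }
  # end of the initial acceleration phase: first + to - crossing
  acc_end <- crossings(1L, i_sys, -1L)
  inf_idx <- NA_integer_
  if (length(acc_end)) {
    up <- crossings(acc_end[1], i_sys, +1L)   # shoulder before the peak
    if (length(up)) inf_idx <- up[1]
  }
  if (is.na(inf_idx)) {
    # post-peak: skip the decay's dP/dt minimum (- to +), then look for
    # a + to - crossing marking a genuine late shoulder
    post_min <- crossings(i_sys, i_end, +1L)
    if (length(post_min)) {
      late <- crossings(post_min[1], i_end, -1L)
      # a genuine late shoulder shows substantial positive curvature
      # between the two crossings; ignore numerical ripples
      # a genuine late shoulder also sits well above the diastolic level
      late <- late[vapply(late, function(j)
        max(d2[post_min[1]:j]) >= 0.02 * d2_scale &&
          Pr[j] >= min(Pr) + 0.15 * PP, logical(1))]
      if (length(late)) inf_idx <- late[1]
    }
  }
  if (is.na(inf_idx)) {
    return(list(AP = NA_real_, AI = NA_real_, t_inflection = NA_real_,
                t_sys = series$t[wrap_idx(lm_$i_foot + i_sys - 1L, n)],
                flagged = TRUE))
  }
  AP <- (Pr[i_sys] - Pr[inf_idx]) * if (inf_idx < i_sys) 1 else -1
  list(AP = AP, AI = AP / PP,
       t_inflection = series$t[wrap_idx(lm_$i_foot + inf_idx - 1L, n)],
       t_sys = series$t[wrap_idx(lm_$i_foot + i_sys - 1L, n)],
       flagged = FALSE)
}

# --- reflection coefficients ---------------------------------------------

#' Reflection coefficient at a bifurcation
#'
#' Forward direction: the daughters act in parallel,
#' `R_p = (Z_d - Z_p) / (Z_d + Z_p)` with `Z_d = (sum 1/Z_i)^-1`.
#' Backward direction (per daughter): the effective impedance seen by a
#' wave arriving up daughter `i` is the parallel of the parent and the
#' other daughters; the bifurcation-level value is the mean of the
#' per-daughter magnitudes.
#'
#' @param Zc_parent parent characteristic impedance (Pa s/m^3).
#' @param Zc_daughters numeric vector of daughter impedances.
#' @param direction `"forward"` or `"backward"`.
#' @return an object of class `pw_rp` with the signed value (forward) or
#'   magnitude-mean (backward, per-daughter values attached).
#' @export
rp_bifurcation <- function(Zc_parent, Zc_daughters,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(Zc_parent > 0, all(Zc_daughters > 0))
  if (direction == "forward") {
    Zd <- 1 / sum(1 / Zc_daughters)
    val <- (Zd - Zc_parent) / (Zd + Zc_parent)
    structure(list(kind = "bifurcation_forward", value = val,
                   Zc_parent = Zc_parent, Zc_daughters = Zc_daughters),
              class = "pw_rp")
  } else {
    per <- vapply(seq_along(Zc_daughters), function(i) {
      others <- Zc_daughters[-i]
      Zeff <- 1 / (1 / Zc_parent + sum(1 / others))
      (Zeff - Zc_daughters[i]) / (Zeff + Zc_daughters[i])
    }, numeric(1))
    structure(list(kind = "bifurcation_backward", value = mean(abs(per)),
                   per_daughter = per,
                   Zc_parent = Zc_parent, Zc_daughters = Zc_daughters),
              class = "pw_rp")
  }
}

#' Cumulative reflection coefficient of a tapered vessel
#'
#' Telescoped sum of the per-interface impedance mismatches along the
#' vessel's cells: `sum_e (Z_{e+1} - Z_e) / (Z_{e+1} + Z_e)`.
#'
#' @param Zc_cells per-cell characteristic impedances, inlet to outlet.
#' @return a `pw_rp` with the signed sum.
#' @export
rp_taper <- function(Zc_cells) {
  stopifnot(length(Zc_cells) >= 1, all(Zc_cells > 0))
  n <- length(Zc_cells)
  val <- if (n == 1) 0 else
    sum((Zc_cells[-1] - Zc_cells[-n]) / (Zc_cells[-1] + Zc_cells[-n]))
  structure(list(kind = "taper", value = val, Zc_cells = Zc_cells),
            class = "pw_rp")
}

#' Reflection coefficient at a terminal branch
#'
#' `R_p = (R_down - Z_c,out) / (R_down + Z_c,out)` where `R_down` is the
#' downstream (Windkessel) resistance and `Z_c,out` the outlet
#' characteristic impedance.
#'
#' @param R_down downstream resistance (Pa s/m^3), `Inf` for a closed end.
#' @param Zc_out outlet characteristic impedance (Pa s/m^3).
#' @return a `pw_rp`.
#' @export
rp_terminal <- function(R_down, Zc_out) {
  stopifnot(Zc_out > 0, R_down >= 0)
  val <- if (is.infinite(R_down)) 1 else
    (R_down - Zc_out) / (R_down + Zc_out)
  structure(list(kind = "terminal", value = val,
                 R_down = R_down, Zc_out = Zc_out),
            class = "pw_rp")
}

#' @export
print.pw_rp <- function(x, ...) {
  cat("<pw_rp> ", x$kind, "  R_p = ", signif(x$value, 4), "\n", sep = "")
  invisible(x)
}

# --- input impedance ------------------------------------------------------

#' Input impedance spectrum from one periodic beat
#'
#' Fourier decomposition of pressure and flow at the harmonics of
#' `1/RR`: `Z_in(f_k) = Phat_k / Qhat_k`.  The DC value uses
#' `(mean(P) - P_reference) / mean(Q)`.  Harmonics whose flow content is
#' below `1e-12` of the flow scale are marked undefined (NA).
#'
#' @param series a `pw_series` spanning exactly one beat.
#' @param P_reference reference (outflow) pressure subtracted at DC (Pa).
#' @param K highest harmonic (>= 12).
#' @return an object of class `pw_impedance` with `f` (Hz), `modulus`
#'   (Pa s/m^3) and `phase` (radians) at harmonics `0..K`.
#' @export
input_impedance <- function(series, P_reference = 0, K = 12L) {
  K <- max(12L, as.integer(K))
  n <- length(series$t)
  if (K >= n / 2) stop("too few samples for ", K, " harmonics")
  Ph <- stats::fft(series$P) / n
  Qh <- stats::fft(series$Q) / n
  f0 <- 1 / series$RR
  qscale <- max(Mod(Qh))
  Z <- complex(length.out = K + 1)
  Z[1] <- (mean(series$P) - P_reference) / mean(series$Q)
  for (k in 1:K) {
    if (Mod(Qh[k + 1]) < 1e-12 * qscale) Z[k + 1] <- NA
    else Z[k + 1] <- Ph[k + 1] / Qh[k + 1]
  }
  structure(list(f = (0:K) * f0, modulus = Mod(Z), phase = Arg(Z)),
            class = "pw_impedance")
}

#' @export
plot.pw_impedance <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$f, x$modulus, type = "b", log = "y",
                 xlab = "f (Hz)", ylab = "|Z_in|", ...)
  graphics::plot(x$f, x$phase, type = "b",
                 xlab = "f (Hz)", ylab = "phase (rad)", ...)
  invisible(x)
}
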
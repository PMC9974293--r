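# Network-level analysis reports built on the per-cell operations, and
# the supine-versus-standing comparison.

#' Per-vessel wave-analysis report
#'
#' Runs the PQ-/PU-loop estimators and wave separation at every cell of
#' every vessel of a converged simulation and aggregates per vessel:
#' wave speed (mean and s.d. over cells), characteristic impedance,
#' mean forward/backward pulse pressures, RM, RI, augmentation index at
#' the mid cell, and the cumulative taper reflection coefficient.
#'
#' @param sim a `pw_sim`.
#' @param rho blood density (defaults to the simulation's).
#' @return a data frame of class `pw_report` (one row per vessel) with a
#'   `cells` attribute holding the per-cell values used for paired
#'   statistics.
#' @export
wave_analysis_report <- function(sim, rho = sim$config$blood_density) {
  net <- sim$network
  percell <- list()
  rows <- lapply(net$vessels, function(v) {
    id <- as.character(v$id)
    cs <- numeric(v$n_cells); zs <- numeric(v$n_cells)
    ppf <- numeric(v$n_cells); ppb <- numeric(v$n_cells)
    seps <- vector("list", v$n_cells)
    for (e in seq_len(v$n_cells)) {
      s <- sim_series(sim, v$id, e)
      cpu <- estimate_c_pu(s, rho)
      zc <- estimate_zc_pq(s)
      sep <- separate_waves(s, zc)
      cs[e] <- cpu$c; zs[e] <- zc$Zc
      ppf[e] <- sep$PP_f; ppb[e] <- sep$PP_b
      seps[[e]] <- sep
    }
    mid <- max(1L, ceiling(v$n_cells / 2))
    refl <- vessel_reflection_indices(seps, sim_series(sim, v$id, mid))
    percell[[id]] <<- data.frame(cell = seq_len(v$n_cells), c = cs,
                                 Zc = zs, PP_f = ppf, PP_b = ppb)
    data.frame(
      vessel_id = v$id, name = v$name, group = v$group,
      n_cells = v$n_cells,
      c_m_s = mean(cs), c_sd = stats::sd(cs),
      Zc = mean(zs),
      PPf_mmHg = Pa_to_mmHg(refl$PP_f), PPb_mmHg = Pa_to_mmHg(refl$PP_b),
      RM = refl$RM, RI = refl$RI, AI = refl$AI,
      Rp_taper = rp_taper(zs)$value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cells") <- percell
  class(out) <- c("pw_report", "data.frame")
  out
}

#' Terminal reflection coefficients of a simulated network
#'
#' For every terminal branch: downstream resistance `R_down = R1 + R2`
#' against the outlet characteristic impedance estimated by the PQ-loop
#' at the last cell.
#'
#' @param sim a `pw_sim`.
#' @return data frame with `vessel_id`, `group`, `R_down`, `Zc_out`, `Rp`.
#' @export
terminal_reflection <- function(sim) {
  net <- sim$network
  rows <- lapply(names(net$terminals), function(id) {
    v <- network_vessel(net, id)
    tm <- net$terminals[[id]]
    s <- sim_series(sim, v$id, v$n_cells)
    Zc <- estimate_zc_pq(s)$Zc
    data.frame(vessel_id = v$id, group = v$group, R_down = tm$R_down,
               Zc_out = Zc, Rp = rp_terminal(tm$R_down, Zc)$value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bifurcation reflection coefficients of a simulated network
#'
#' For every true bifurcation: forward and backward reflection
#' coefficients from the PQ-loop impedances at the parent's distal cell
#' and the daughters' proximal cells.  Impedances may alternatively be
#' taken from the rigid reference state (`use = "reference"`), which
#' needs no simulation.
#'
#' @param sim a `pw_sim`, or a `pw_network` when `use = "reference"`.
#' @param use `"loop"` (PQ-loop estimates) or `"reference"` (tube-law
#'   impedance at the reference pressure).
#' @param rho,P_ref reference-state parameters for `use = "reference"`.
#' @return data frame with `parent`, `Rp_forward`, `Rp_backward`.
#' @export
bifurcation_reflection <- function(sim, use = c("loop", "reference"),
                                   rho = 1050, P_ref = mmHg_to_Pa(100)) {
  use <- match.arg(use)
  net <- if (inherits(sim, "pw_network")) sim else sim$network
  if (use == "loop" && !inherits(sim, "pw_sim"))
    stop("loop impedances need a simulation")
  rows <- list()
  for (j in net$junctions) {
    if (length(j$daughters) < 2) next
    pv <- network_vessel(net, j$parent)
    if (use == "loop") {
      Zp <- estimate_zc_pq(sim_series(sim, pv$id, pv$n_cells))$Zc
      Zd <- vapply(j$daughters, function(d)
        estimate_zc_pq(sim_series(sim, d, 1L))$Zc, numeric(1))
    } else {
      Zp <- reference_impedance(pv, rho, P_ref, x = pv$length)
      Zd <- vapply(j$daughters, function(d) {
        dv <- network_vessel(net, d)
        reference_impedance(dv, rho, P_ref, x = 0)
      }, numeric(1))
    }
    rows[[length(rows) + 1]] <- data.frame(
      parent = j$parent,
      Rp_forward = rp_bifurcation(Zp, Zd, "forward")$value,
      Rp_backward = rp_bifurcation(Zp, Zd, "backward")$value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare wave metrics between two postures
#'
#' Joins two [wave_analysis_report()] tables (same network) and reports,
#' per vessel, the percentage change of wave speed and pulse pressures
#' plus the paired Wilcoxon p-value of the per-cell wave speeds.
#'
#' @param supine,standing `pw_report` objects from the two postures.
#' @return data frame of class `pw_posture_comparison`.
#' @export
compare_posture <- function(supine, standing) {
  stopifnot(inherits(supine, "pw_report"), inherits(standing, "pw_report"))
  if (!identical(supine$vessel_id, standing$vessel_id))
    stop("reports cover different vessels")
  cs <- attr(supine, "cells"); ct <- attr(standing, "cells")
  rows <- lapply(seq_len(nrow(supine)), function(i) {
    id <- as.character(supine$vessel_id[i])
    w <- wilcoxon_signed_rank(cs[[id]]$c, ct[[id]]$c)
    data.frame(
      vessel_id = supine$vessel_id[i], name = supine$name[i],
      group = supine$group[i], n = w$n,
      c_supine = supine$c_m_s[i], c_standing = standing$c_m_s[i],
      delta_c_pct = percent_change(supine$c_m_s[i], standing$c_m_s[i]),
      p_c = w$p,
      delta_PPf_pct = percent_change(supine$PPf_mmHg[i], standing$PPf_mmHg[i]),
      delta_PPb_pct = percent_change(supine$PPb_mmHg[i], standing$PPb_mmHg[i]),
      RM_supine = supine$RM[i], RM_standing = standing$RM[i],
      delta_RM_pct = percent_change(supine$RM[i], standing$RM[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pw_posture_comparison", "data.frame")
  out
}
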
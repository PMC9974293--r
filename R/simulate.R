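# Driver for the compiled 1D solver: runs beats to periodic convergence
# and wraps the converged beat at every cell midpoint.

#' Simulate heartbeats on an arterial network to periodic convergence
#'
#' Advances the one-dimensional mass/momentum equations on the network,
#' with gravity scaled by the posture tilt, prescribed periodic root
#' inflow and RCR Windkessel terminals, until the beat-to-beat relative
#' L2 pressure change at the monitored nodes falls below
#' `sim$convergence_tol` (or `sim$max_beats` is reached, in which case a
#' warning is issued and `converged = FALSE` is reported).
#'
#' Terminal outflow pressures gain the local hydrostatic column
#' (`P_out + rho g z sin(tilt)`), mirroring the hydrostatic term carried
#' by the downstream microvascular compartments, so that perfusion is
#' driven by the heart-level pressure difference at any tilt.
#'
#' @param network a `pw_network`.
#' @param inflow a `pw_inflow` attached at the root vessel.
#' @param posture a [posture_state()], a tilt angle in degrees, or `NULL`
#'   for supine (0 degrees).  A full `pw_posture` is applied to the
#'   network and inflow first (see [apply_posture()]).
#' @param sim a [sim_config()].
#' @param P_init initial uniform (heart-level) pressure (Pa); defaults to
#'   the network's DC operating point `P_out + mean flow x TPR`.
#' @return an object of class `pw_sim`: converged-beat series for every
#'   cell (see [sim_series()]), the network and inflow actually
#'   simulated, and a `pw_convergence` report.
#' @export
simulate_beats <- function(network, inflow, posture = NULL,
                           sim = sim_config(), P_init = NULL) {
  stopifnot(inherits(network, "pw_network"), inherits(inflow, "pw_inflow"))
  tilt <- 0
  if (inherits(posture, "pw_posture")) {
    ap <- apply_posture(network, inflow, posture)
    network <- ap$network
    inflow <- ap$inflow
    tilt <- posture$theta
  } else if (is.numeric(posture) && length(posture) == 1) {
    tilt <- posture
  } else if (!is.null(posture)) {
    stop("posture must be a pw_posture, a tilt angle, or NULL")
  }
  if (abs(tilt) > 90) stop("|tilt| must be <= 90 degrees")

  if (is.null(P_init)) {
    qbar <- inflow$SV / inflow$RR
    pouts <- vapply(network$terminals, function(tm) tm$P_out, numeric(1))
    P_init <- mean(pouts) + qbar * total_peripheral_resistance(network)
  }

  ids <- vapply(network$vessels, function(v) v$id, integer(1))
  vlist <- lapply(network$vessels, function(v)
    list(n_cells = v$n_cells, length = v$length, A0_prox = v$A0_prox,
         A0_dist = v$A0_dist, beta = v$beta, Gamma = v$Gamma,
         phi = v$phi, z_prox = v$z_prox))
  idx_of <- function(id) match(as.integer(id), ids)
  jp <- vapply(network$junctions, function(j) idx_of(j$parent), integer(1))
  jd <- lapply(network$junctions, function(j)
    as.integer(vapply(j$daughters, idx_of, integer(1))))
  tlist <- lapply(names(network$terminals), function(id) {
    tm <- network$terminals[[id]]
    list(vessel = idx_of(id), R1 = tm$R1, R2 = tm$R2, C = tm$C,
         Pout = tm$P_out)
  })

  simlist <- unclass(sim)
  simlist$tilt_deg <- tilt

  # monitored nodes: root inlet cell, a mid-network cell, one terminal cell
  root_i <- idx_of(network$root)
  mid_id <- if (!is.null(network$aortic_path))
    network$aortic_path[ceiling(length(network$aortic_path) / 2)]
  else network$root
  mid_i <- idx_of(mid_id)
  term_i <- idx_of(names(network$terminals)[1])
  monitors <- rbind(
    c(root_i, 1L),
    c(mid_i, max(1L, network$vessels[[mid_i]]$n_cells %/% 2)),
    c(term_i, network$vessels[[term_i]]$n_cells))

  res <- .pw_solve(vlist, as.integer(jp), jd, tlist, root_i,
                   inflow$t, inflow$Q, inflow$RR, simlist,
                   monitors, P_init)

  if (!res$converged)
    warning("simulation did not reach periodic convergence in ",
            res$beats_run, " beats (last change ",
            signif(utils::tail(res$beat_change, 1), 3), ")")

  convergence <- structure(list(
    beats_run = res$beats_run,
    beat_change = res$beat_change,
    converged = res$converged,
    tol = sim$convergence_tol,
    max_junction_residual = res$max_junction_residual
  ), class = "pw_convergence")

  structure(list(
    t = res$t,
    P = stats::setNames(res$P, as.character(ids)),
    Q = stats::setNames(res$Q, as.character(ids)),
    A = stats::setNames(res$A, as.character(ids)),
    network = network,
    inflow = inflow,
    tilt = tilt,
    config = sim,
    convergence = convergence
  ), class = "pw_sim")
}

#' Extract one cell's converged beat as a time-series object
#'
#' @param sim a `pw_sim`.
#' @param vessel vessel id.
#' @param cell cell index (1..n_cells).
#' @return an object of class `pw_series` with fields `t`, `P` (Pa),
#'   `Q` (m^3/s), `A` (m^2), `U` (m/s), `RR`, and location metadata
#'   (`vessel`, `cell`, `x` from the vessel inlet, `z` below heart level
#'   upright).
#' @export
sim_series <- function(sim, vessel, cell) {
  key <- as.character(vessel)
  if (!key %in% names(sim$P)) stop("vessel ", vessel, " not in simulation")
  v <- network_vessel(sim$network, vessel)
  cell <- as.integer(cell)
  if (cell < 1 || cell > v$n_cells) stop("cell out of range")
  x <- vessel_cell_x(v)[cell]
  hemo_series(t = sim$t,
              P = sim$P[[key]][cell, ],
              Q = sim$Q[[key]][cell, ],
              A = sim$A[[key]][cell, ],
              RR = sim$inflow$RR,
              vessel = v$id, cell = cell, x = x,
              z = vessel_z_at(v, x))
}

#' Construct a haemodynamic beat series
#'
#' Container for one converged beat of pressure/flow/area at a point,
#' used by every analysis routine.  `U` is derived as `Q/A` when both
#' are present; analysis-only tables may omit `A` (then PQ-based
#' operations remain available but PU-based ones error).
#'
#' @param t uniform time grid over one beat (s).
#' @param P pressure (Pa).
#' @param Q flow (m^3/s).
#' @param A area (m^2) or `NULL`.
#' @param RR beat period (s).
#' @param vessel,cell,x,z location metadata.
#' @return a `pw_series`.
#' @export
hemo_series <- function(t, P, Q, A = NULL, RR = max(t) + (t[2] - t[1]),
                        vessel = NA_integer_, cell = NA_integer_,
                        x = NA_real_, z = NA_real_) {
  n <- length(t)
  if (n < 64) stop("a beat series needs at least 64 samples")
  if (length(P) != n || length(Q) != n)
    stop("t, P, Q must have equal length")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time grid must be uniform")
  if (!is.null(A)) {
    if (length(A) != n) stop("A must match t in length")
    if (any(A <= 0)) stop("areas must be positive")
  }
  U <- if (!is.null(A)) Q / A else NULL
  if (!is.null(U) && any(!is.finite(U))) stop("non-finite velocity")
  structure(list(t = t, P = P, Q = Q, A = A, U = U, RR = RR,
                 vessel = vessel, cell = cell, x = x, z = z),
            class = "pw_series")
}

#' @export
print.pw_series <- function(x, ...) {
  cat("<pw_series> vessel ", x$vessel, " cell ", x$cell,
      "  (", length(x$t), " samples, RR=", signif(x$RR, 4), "s)\n",
      "  P [mmHg]: ", paste(signif(Pa_to_mmHg(range(x$P)), 4), collapse = " .. "),
      "\n  Q [ml/s]: ", paste(signif(range(x$Q) * 1e6, 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.pw_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t / x$RR, Pa_to_mmHg(x$P), type = "l",
                 xlab = "t / RR", ylab = "P (mmHg)", ...)
  graphics::plot(x$t / x$RR, x$Q * 1e6, type = "l",
                 xlab = "t / RR", ylab = "Q (ml/s)", ...)
  invisible(x)
}

#' @export
print.pw_convergence <- function(x, ...) {
  cat("<pw_convergence> beats=", x$beats_run,
      " converged=", x$converged,
      " last_change=", signif(utils::tail(x$beat_change, 1), 3),
      " (tol ", x$tol, ")\n",
      " max junction mass residual: ",
      signif(x$max_junction_residual, 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.pw_sim <- function(x, ...) {
  cat("<pw_sim> ", x$network$name, " at tilt ", x$tilt, " deg\n", sep = "")
  print(x$convergence)
  invisible(x)
}

#' @export
summary.pw_sim <- function(object, ...) {
  ids <- names(object$P)
  df <- do.call(rbind, lapply(ids, function(id) {
    v <- network_vessel(object$network, id)
    P <- object$P[[id]]
    data.frame(vessel_id = v$id, name = v$name, group = v$group,
               n_cells = v$n_cells,
               mean_P_mmHg = Pa_to_mmHg(mean(P)),
               pulse_P_mmHg = Pa_to_mmHg(mean(apply(P, 1, function(p)
                 max(p) - min(p)))))
  }))
  df
}

#' Hydrostatic pressure offset under tilt
#'
#' `dP = rho g dz sin(tilt)`, positive below heart level.
#'
#' @param dz elevation below heart level in the upright body (m).
#' @param tilt head-up tilt angle (degrees, 0 = supine, 90 = standing).
#' @param rho blood density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @return pressure offset (Pa).
#' @export
hydrostatic_offset <- function(dz, tilt, rho = 1050, g = 9.81) {
  if (any(abs(tilt) > 90)) stop("|tilt| must be <= 90 degrees")
  rho * g * dz * sin(tilt * pi / 180)
}

#' Periodic-convergence check on consecutive beats
#'
#' Given consecutive beats of pressure at monitored nodes, computes the
#' per-beat relative L2 change and flags convergence when the last
#' change over all nodes falls below `tol`.
#'
#' @param beats a list of matrices (nodes x samples), one per beat, or a
#'   list of numeric vectors for a single node.
#' @param tol relative L2 tolerance.
#' @return a `pw_convergence` report.
#' @export
check_periodic_convergence <- function(beats, tol = 1e-3) {
  if (length(beats) < 2) stop("need at least 2 beats")
  beats <- lapply(beats, function(b) if (is.matrix(b)) b else matrix(b, 1))
  chg <- vapply(seq_along(beats)[-1], function(k) {
    a <- beats[[k - 1]]; b <- beats[[k]]
    max(vapply(seq_len(nrow(a)), function(i) {
      den <- sqrt(sum(a[i, ]^2))
      if (den == 0) return(if (all(b[i, ] == a[i, ])) 0 else Inf)
      sqrt(sum((b[i, ] - a[i, ])^2)) / den
    }, numeric(1)))
  }, numeric(1))
  structure(list(beats_run = length(beats),
                 beat_change = chg,
                 converged = utils::tail(chg, 1) < tol,
                 tol = tol,
                 max_junction_residual = NA_real_),
            class = "pw_convergence")
}

#' Characteristic junction matching (single evaluation)
#'
#' Solves the coupled boundary state at a junction: mass conservation
#' and continuity of total pressure `P + rho U^2 / 2`, with one outgoing
#' characteristic per connected vessel end.  Exposed mainly for
#' verification; the time-stepping solver calls the same routine
#' internally each step.
#'
#' @param parent `list(beta, A0, W)` where `W = U + 4c` is the incoming
#'   (forward) characteristic at the parent outlet.
#' @param daughters list of `list(beta, A0, W)` with `W = U - 4c` at each
#'   daughter inlet.
#' @param rho blood density.
#' @return list with matched `A`, `Q`, `P` per vessel and the relative
#'   mass residual.
#' @export
junction_match <- function(parent, daughters, rho = 1050) {
  .pw_junction_match(parent, daughters, rho)
}
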
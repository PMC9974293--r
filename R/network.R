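# Arterial network data model: vessels, junctions, Windkessel terminals,
# inflow source, and the rooted-tree topology that ties them together.

#' Solver and physical configuration
#'
#' Collects blood properties, gravity, and numerical settings for the
#' one-dimensional pulse solver.
#'
#' @param blood_density blood density rho (kg/m^3).
#' @param blood_viscosity dynamic viscosity mu (Pa s).
#' @param gravity gravitational acceleration g (m/s^2).
#' @param momentum_correction dimensionless momentum-flux correction alpha.
#' @param friction_coefficient viscous source coefficient K_R (m^2/s).
#'   The default `22 * pi * mu / rho` corresponds to a Womersley-motivated
#'   flat-core velocity profile with profile constant 22.
#' @param cfl Courant number in (0, 1].
#' @param max_beats maximum number of heartbeats to run towards a periodic
#'   state.
#' @param convergence_tol relative L2 beat-to-beat pressure change below
#'   which the solution is declared periodic.
#' @param sample_rate output sampling rate (Hz) for the converged beat.
#' @return an object of class `pw_config` (a validated list).
#' @export
sim_config <- function(blood_density = 1050,
                       blood_viscosity = 0.004,
                       gravity = 9.81,
                       momentum_correction = 1.0,
                       friction_coefficient = 22 * pi * blood_viscosity / blood_density,
                       cfl = 0.9,
                       max_beats = 30L,
                       convergence_tol = 1e-3,
                       sample_rate = 1000) {
  stopifnot(blood_density > 0, blood_viscosity > 0, gravity > 0,
            momentum_correction > 0, friction_coefficient >= 0,
            cfl > 0, cfl <= 1, max_beats >= 1,
            convergence_tol > 0, sample_rate > 0)
  structure(list(
    blood_density = blood_density,
    blood_viscosity = blood_viscosity,
    gravity = gravity,
    momentum_correction = momentum_correction,
    friction_coefficient = friction_coefficient,
    cfl = cfl,
    max_beats = as.integer(max_beats),
    convergence_tol = convergence_tol,
    sample_rate = sample_rate
  ), class = "pw_config")
}

#' Define a one-dimensional vessel segment
#'
#' A vessel is a linearly tapered elastic (optionally visco-elastic) tube
#' discretized into `n_cells` segments.  Orientation follows the upright
#' body: `phi` is the inclination from horizontal with positive sign when
#' the distal end lies below the proximal end at 90 degrees tilt, and
#' `z_prox` is the proximal elevation relative to heart level at 90
#' degrees tilt, positive below the heart.
#'
#' @param id integer vessel identifier.
#' @param name text label.
#' @param length vessel length (m).
#' @param A0_prox,A0_dist proximal/distal reference (zero transmural
#'   pressure) cross-section areas (m^2); the reference area tapers
#'   linearly in between.
#' @param beta elastic tube-law stiffness coefficient (Pa m).
#' @param Gamma visco-elastic (Voigt) coefficient (Pa s m).
#' @param phi inclination (degrees from horizontal when upright).
#' @param z_prox proximal elevation below heart level when upright (m).
#' @param group one of `"aortic"`, `"cerebral"`, `"limb"`, `"other"`.
#' @param n_cells number of discretization cells (>= 2).
#' @return an object of class `pw_vessel`.
#' @export
vessel_segment <- function(id, name = paste0("vessel_", id), length,
                           A0_prox, A0_dist = A0_prox, beta, Gamma = 0,
                           phi = 0, z_prox = 0, group = "other",
                           n_cells = 4L) {
  id <- as.integer(id)
  n_cells <- as.integer(n_cells)
  if (!(length > 0)) stop("vessel ", id, ": length must be > 0")
  if (!(A0_prox > 0 && A0_dist > 0)) stop("vessel ", id, ": A0 must be > 0")
  if (!(beta > 0)) stop("vessel ", id, ": beta must be > 0")
  if (Gamma < 0) stop("vessel ", id, ": Gamma must be >= 0")
  if (n_cells < 2) stop("vessel ", id, ": n_cells must be >= 2")
  if (abs(phi) > 90) stop("vessel ", id, ": |phi| must be <= 90 degrees")
  group <- match.arg(group, c("aortic", "cerebral", "limb", "other"))
  structure(list(
    id = id, name = name, length = length,
    A0_prox = A0_prox, A0_dist = A0_dist,
    beta = beta, Gamma = Gamma,
    phi = phi, z_prox = z_prox,
    group = group, n_cells = n_cells
  ), class = "pw_vessel")
}

#' Terminal RCR Windkessel element
#'
#' @param R1 proximal resistance (Pa s/m^3).
#' @param R2 distal resistance (Pa s/m^3).
#' @param C compliance (m^3/Pa); `C = 0` degenerates to a purely resistive
#'   load.
#' @param P_out outflow (venous-side) pressure at heart level (Pa).
#' @return an object of class `pw_terminal` with derived `R_down = R1 + R2`.
#' @export
terminal_windkessel <- function(R1, R2, C = 0, P_out = 0) {
  if (R1 < 0 || R2 < 0 || C < 0) stop("R1, R2, C must be >= 0")
  if (!(R1 + R2 > 0)) stop("R_down = R1 + R2 must be > 0")
  structure(list(R1 = R1, R2 = R2, C = C, P_out = P_out,
                 R_down = R1 + R2),
            class = "pw_terminal")
}

# local reference area at axial position x (linear taper)
vessel_A0_at <- function(vessel, x) {
  s <- pmin(pmax(x / vessel$length, 0), 1)
  vessel$A0_prox + (vessel$A0_dist - vessel$A0_prox) * s
}

# cell midpoints of a vessel
vessel_cell_x <- function(vessel) {
  dx <- vessel$length / vessel$n_cells
  (seq_len(vessel$n_cells) - 0.5) * dx
}

# elevation (m below heart, upright geometry) at axial position x
vessel_z_at <- function(vessel, x) {
  vessel$z_prox + x * sin(vessel$phi * pi / 180)
}

#' Pressure from the constitutive tube law
#'
#' Elastic beta-law with a Voigt visco-elastic term:
#' `P = P_ext + (beta / A0) * (sqrt(A) - sqrt(A0)) + Gamma / (A0 sqrt(A)) * dA/dt`
#' where `A0` is the local (taper-interpolated) reference area.  The
#' elastic branch is strictly monotone increasing in `A`, which yields a
#' closed-form wave speed (see [wave_speed()]).
#'
#' @param A cross-section area (m^2), may be a vector.
#' @param dA_dt area rate of change (m^2/s).
#' @param vessel a [vessel_segment()].
#' @param x axial position of the evaluation point (m from the vessel
#'   inlet); defaults to mid-vessel.
#' @param P_ext external pressure (Pa).
#' @return pressure (Pa), same length as `A`.
#' @export
tube_law <- function(A, dA_dt = 0, vessel, x = vessel$length / 2,
                     P_ext = 0) {
  if (any(A <= 0)) stop("numerical-state error: non-positive area in tube law")
  A0 <- vessel_A0_at(vessel, x)
  P_ext + (vessel$beta / A0) * (sqrt(A) - sqrt(A0)) +
    vessel$Gamma / (A0 * sqrt(A)) * dA_dt
}

#' Inverse elastic tube law: area at a given transmural pressure
#'
#' @param P transmural pressure (Pa).
#' @inheritParams tube_law
#' @return area (m^2).
#' @export
tube_law_area <- function(P, vessel, x = vessel$length / 2, P_ext = 0) {
  A0 <- vessel_A0_at(vessel, x)
  sa <- sqrt(A0) + (P - P_ext) * A0 / vessel$beta
  if (any(sa <= 0)) stop("pressure below collapse limit of the elastic tube law")
  sa^2
}

#' Analytic wave speed of the elastic tube law
#'
#' `c = sqrt((A / rho) dP/dA)` evaluated on the elastic branch, which for
#' the beta-law gives `c = sqrt(beta / (2 rho A0)) * A^(1/4)`.
#'
#' @param A cross-section area (m^2).
#' @param vessel a [vessel_segment()].
#' @param rho blood density (kg/m^3).
#' @param x axial position (m); defaults to mid-vessel.
#' @return wave speed (m/s).
#' @export
wave_speed <- function(A, vessel, rho = 1050, x = vessel$length / 2) {
  if (any(A <= 0)) stop("non-positive area")
  A0 <- vessel_A0_at(vessel, x)
  sqrt(vessel$beta / (2 * rho * A0)) * A^0.25
}

#' Assemble and validate an arterial network
#'
#' Builds a rooted-tree arterial network from its parts and checks the
#' structural invariants: connected rooted tree, every non-root vessel a
#' daughter exactly once, every leaf carrying exactly one terminal
#' Windkessel, and the aortic path (when given) a root-to-leaf-directed
#' chain.
#'
#' @param vessels list of [vessel_segment()] objects.
#' @param junctions list of `list(parent = id, daughters = c(id, ...))`
#'   entries; one daughter encodes an anatomical continuation, two a
#'   bifurcation.
#' @param terminals named list mapping leaf vessel id (as character) to
#'   [terminal_windkessel()] objects.
#' @param root id of the root vessel (inflow attachment).
#' @param aortic_path optional ordered vector of vessel ids from the root
#'   towards the iliac bifurcation.
#' @param name optional network label.
#' @return an object of class `pw_network`.
#' @export
build_network <- function(vessels, junctions = list(), terminals,
                          root, aortic_path = NULL, name = "network") {
  ids <- vapply(vessels, function(v) v$id, integer(1))
  if (anyDuplicated(ids))
    stop("configuration error: duplicate vessel ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(vessels) <- as.character(ids)
  root <- as.integer(root)
  if (!root %in% ids) stop("configuration error: root vessel ", root, " not defined")

  parent_of <- integer(0)
  for (j in junctions) {
    p <- as.integer(j$parent); ds <- as.integer(j$daughters)
    if (!p %in% ids)
      stop("configuration error: junction parent ", p, " not defined")
    if (length(ds) < 1 || length(ds) > 2)
      stop("configuration error: junction of vessel ", p,
           " must have 1 or 2 daughters")
    if (any(!ds %in% ids))
      stop("configuration error: daughter vessel ",
           paste(ds[!ds %in% ids], collapse = ", "), " not defined")
    if (p %in% ds) stop("topology error: vessel ", p, " is its own daughter")
    for (d in ds) {
      if (as.character(d) %in% names(parent_of))
        stop("topology error: vessel ", d, " appears as daughter more than once")
      parent_of[as.character(d)] <- p
    }
  }
  if (as.character(root) %in% names(parent_of))
    stop("topology error: root vessel ", root, " appears as a daughter")

  # connectivity + acyclicity by walk from root
  children <- lapply(junctions, function(j) as.integer(j$daughters))
  names(children) <- vapply(junctions, function(j) as.character(j$parent), "")
  seen <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% seen) stop("topology error: cycle detected at vessel ", v)
    seen <- c(seen, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  orphan <- setdiff(ids, seen)
  if (length(orphan))
    stop("topology error: vessels not reachable from root: ",
         paste(orphan, collapse = ", "))

  leaves <- setdiff(ids, as.integer(names(children)))
  term_ids <- as.integer(names(terminals))
  missing_t <- setdiff(leaves, term_ids)
  if (length(missing_t))
    stop("configuration error: leaf vessels without a terminal: ",
         paste(missing_t, collapse = ", "))
  extra_t <- setdiff(term_ids, leaves)
  if (length(extra_t))
    stop("configuration error: terminals attached to non-leaf vessels: ",
         paste(extra_t, collapse = ", "))
  for (tm in terminals)
    if (!inherits(tm, "pw_terminal")) stop("terminals must be pw_terminal objects")

  if (!is.null(aortic_path)) {
    aortic_path <- as.integer(aortic_path)
    if (aortic_path[1] != root)
      stop("configuration error: aortic path must start at the root")
    for (k in seq_along(aortic_path)[-1]) {
      kids <- children[[as.character(aortic_path[k - 1])]]
      if (is.null(kids) || !aortic_path[k] %in% kids)
        stop("configuration error: aortic path is not a directed chain at vessel ",
             aortic_path[k])
    }
  }

  structure(list(
    name = name,
    vessels = vessels,
    junctions = junctions,
    terminals = terminals,
    root = root,
    aortic_path = aortic_path
  ), class = "pw_network")
}

#' @export
print.pw_network <- function(x, ...) {
  nb <- sum(vapply(x$junctions, function(j) length(j$daughters) == 2, logical(1)))
  cat("<pw_network> ", x$name, "\n",
      "  vessels:   ", length(x$vessels), "\n",
      "  junctions: ", length(x$junctions), " (", nb, " bifurcations)\n",
      "  terminals: ", length(x$terminals), "\n",
      "  root:      ", x$root, "\n", sep = "")
  if (!is.null(x$aortic_path))
    cat("  aortic path: ", paste(x$aortic_path, collapse = " > "), "\n", sep = "")
  invisible(x)
}

network_vessel <- function(network, id) {
  v <- network$vessels[[as.character(id)]]
  if (is.null(v)) stop("vessel ", id, " not in network")
  v
}

#' Total peripheral resistance of a network
#'
#' Parallel combination of all terminal downstream resistances
#' `R_down = R1 + R2`.
#'
#' @param network a `pw_network`.
#' @return total resistance (Pa s/m^3).
#' @export
total_peripheral_resistance <- function(network) {
  1 / sum(vapply(network$terminals, function(tm) 1 / tm$R_down, numeric(1)))
}

#' Beat-averaged daughter-to-parent area ratio at a bifurcation
#'
#' Computes `A_d / A_p` as the sum of beat-mean daughter areas (at the
#' daughters' proximal cells) over the beat-mean parent area (at the
#' parent's distal cell).  Continuation junctions (a single daughter) are
#' excluded from the network mean with a notice.
#'
#' @param junction a junction entry (`list(parent, daughters)`).
#' @param parent_A beat series (numeric vector) of the parent distal-cell
#'   area; a constant can be supplied for a rigid reference state.
#' @param daughter_A list of beat series of the daughters' proximal-cell
#'   areas.
#' @return the dimensionless ratio.
#' @export
area_ratio_bifurcation <- function(junction, parent_A, daughter_A) {
  if (length(junction$daughters) < 2) {
    message("junction of vessel ", junction$parent,
            " is a continuation; excluded from area-ratio statistics")
    return(NA_real_)
  }
  sum(vapply(daughter_A, mean, numeric(1))) / mean(parent_A)
}

#' Network-mean bifurcation area ratio
#'
#' Averages [area_ratio_bifurcation()] over all true bifurcations, using
#' beat series from a simulation when given, else the rigid reference
#' areas.
#'
#' @param network a `pw_network`.
#' @param sim optional `pw_sim` result providing beat-varying areas; when
#'   absent the rigid reference state (areas at `P_ref`) is used.
#' @param P_ref reference pressure (Pa) for the rigid state.
#' @return list with per-junction ratios and their mean.
#' @export
network_area_ratios <- function(network, sim = NULL,
                                P_ref = mmHg_to_Pa(100)) {
  ratios <- numeric(0)
  parents <- integer(0)
  for (j in network$junctions) {
    if (length(j$daughters) < 2) next
    pv <- network_vessel(network, j$parent)
    if (is.null(sim)) {
      pA <- tube_law_area(P_ref, pv, x = pv$length)
      dA <- lapply(j$daughters, function(d) {
        dv <- network_vessel(network, d)
        tube_law_area(P_ref, dv, x = 0)
      })
    } else {
      pA <- sim_series(sim, j$parent, pv$n_cells)$A
      dA <- lapply(j$daughters, function(d) sim_series(sim, d, 1L)$A)
    }
    ratios <- c(ratios, area_ratio_bifurcation(j, pA, dA))
    parents <- c(parents, j$parent)
  }
  list(parent = parents, ratio = ratios, mean = mean(ratios))
}

#' Reference characteristic impedance of a vessel cross-section
#'
#' `Z_c = rho c / A` evaluated from the elastic tube law at the area
#' corresponding to a reference pressure.
#'
#' @param vessel a [vessel_segment()].
#' @param rho blood density (kg/m^3).
#' @param P_ref reference transmural pressure (Pa).
#' @param x axial position (m).
#' @return impedance (Pa s/m^3).
#' @export
reference_impedance <- function(vessel, rho = 1050,
                                P_ref = mmHg_to_Pa(100),
                                x = vessel$length / 2) {
  A <- tube_law_area(P_ref, vessel, x)
  rho * wave_speed(A, vessel, rho, x) / A
}
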
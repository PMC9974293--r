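# Bundled canonical networks.  All fixtures are generated in code from a
# handful of physiological targets; geometry is stated at a reference
# pressure of 100 mmHg and converted to tube-law parameters analytically.
#
# For the beta tube law the wave speed at transmural pressure P is
#   c(P) = sqrt((b + P) / (2 rho)),  b = beta / sqrt(A0),
# so a vessel can be specified by its radius and target wave speed at the
# reference pressure and solved for (A0, beta) in closed form.

# tube-law parameters from radius (m) and wave speed (m/s) at P_ref
params_from_targets <- function(r_ref, c_ref, rho = 1050,
                                P_ref = mmHg_to_Pa(100)) {
  b <- 2 * rho * c_ref^2 - P_ref
  if (b <= 0) stop("target wave speed too low for reference pressure")
  A_ref <- pi * r_ref^2
  A0 <- (sqrt(A_ref) / (1 + P_ref / b))^2
  list(b = b, A0 = A0)
}

#' Build a vessel from radius and wave-speed targets
#'
#' Convenience builder: the vessel's reference areas and stiffness are
#' solved so that its lumen radius and elastic wave speed equal the
#' given values at the reference pressure.
#'
#' @param id,name,length,phi,z_prox,group,n_cells,Gamma as in
#'   [vessel_segment()].
#' @param r_prox,r_dist lumen radii (m) at the reference pressure.
#' @param c_ref target wave speed (m/s) at the reference pressure.
#' @param rho blood density (kg/m^3).
#' @param P_ref reference transmural pressure (Pa).
#' @return a `pw_vessel`.
#' @export
vessel_from_targets <- function(id, name, length, r_prox, r_dist, c_ref,
                                phi = 0, z_prox = 0, group = "other",
                                n_cells = 4L, rho = 1050,
                                P_ref = mmHg_to_Pa(100), Gamma = 0) {
  pp <- params_from_targets(r_prox, c_ref, rho, P_ref)
  pd <- params_from_targets(r_dist, c_ref, rho, P_ref)
  A0_mid <- (pp$A0 + pd$A0) / 2
  vessel_segment(id, name, length,
                 A0_prox = pp$A0, A0_dist = pd$A0,
                 beta = pp$b * sqrt(A0_mid), Gamma = Gamma,
                 phi = phi, z_prox = z_prox, group = group,
                 n_cells = n_cells)
}

# anechoic terminal: R1 equal to the outlet characteristic impedance,
# R2 = 0, C = 0; P_out places the working point at P_mean for mean_flow
anechoic_terminal <- function(vessel, rho, mean_flow,
                              P_mean = mmHg_to_Pa(100)) {
  Zc <- reference_impedance(vessel, rho, P_mean, x = vessel$length)
  terminal_windkessel(R1 = Zc, R2 = 0, C = 0,
                      P_out = P_mean - mean_flow * Zc)
}

#' Bundled canonical arterial networks
#'
#' Construct one of the package's reference networks by name:
#'
#' * `"uniform_tube"`: one untapered vessel terminated anechoically
#'   (first Windkessel resistance equal to the outlet characteristic
#'   impedance, no distal resistance or compliance, outflow pressure set
#'   so the working point sits at `P_mean`).  The reflection-free
#'   oracle fixture.
#' * `"tapered_tube"`: one vessel whose reference area halves from inlet
#'   to outlet, anechoic termination at the outlet impedance.
#' * `"murray_tree"`: symmetric bifurcating tree of depth `depth` with
#'   daughter radii `2^(-1/3)` times the parent's (Murray's law) and
#'   per-level stiffness solved so forward characteristic impedance is
#'   matched at every junction.
#' * `"single_reflector"`: a uniform line with an abrupt characteristic
#'   impedance step (factor `z_step`) at distance `reflector_at`,
#'   anechoic beyond it.  The echo-timing oracle fixture.
#' * `"mini_aorta"`: a 14-vessel reduced adult arterial tree carrying the
#'   conventional site numbering along the aortic path
#'   (1, 63, 2, 14, 18, 27, 28, 35, 37, 39, 41) plus a cerebral-tagged
#'   carotid branch (13), an arm branch (24) and a leg branch (48), with
#'   upright elevations from -0.2 m (carotid tip) to +1.2 m (tibial
#'   tip) relative to heart level and RCR Windkessel terminals sized for
#'   a mean aortic pressure of ~93 mmHg at a cardiac output of 87.5 ml/s.
#'
#' @param name one of `"uniform_tube"`, `"tapered_tube"`, `"murray_tree"`,
#'   `"mini_aorta"`, `"single_reflector"`.
#' @param rho blood density (kg/m^3), used to convert wave-speed targets
#'   into stiffness.
#' @param mean_flow beat-mean inflow (m^3/s) used to place anechoic
#'   terminals at their working pressure (tube fixtures only).
#' @param P_mean working mean pressure (Pa) for the tube fixtures.
#' @param depth bifurcation depth of the Murray tree (>= 1).
#' @param reflector_at distance of the impedance step from the inlet (m).
#' @param z_step characteristic-impedance ratio across the step.
#' @param L,r,c_ref length (m), reference radius (m) and wave-speed
#'   target (m/s) for the tube fixtures.
#' @return a `pw_network`.
#' @export
canonical_network <- function(name,
                              rho = 1050,
                              mean_flow = 6.25e-6,
                              P_mean = mmHg_to_Pa(100),
                              depth = 2L,
                              reflector_at = 0.4,
                              z_step = 1.15,
                              L = 1.0, r = 0.01, c_ref = 8) {
  name <- match.arg(name, c("uniform_tube", "tapered_tube", "murray_tree",
                            "mini_aorta", "single_reflector"))
  switch(name,
    uniform_tube = {
      v <- vessel_from_targets(1L, "uniform tube", L, r, r, c_ref,
                               n_cells = max(8L, round(L / 0.02)),
                               rho = rho, P_ref = P_mean)
      build_network(list(v), junctions = list(),
                    terminals = list("1" = anechoic_terminal(v, rho, mean_flow, P_mean)),
                    root = 1L, aortic_path = 1L, name = "uniform_tube")
    },
    tapered_tube = {
      v <- vessel_from_targets(1L, "tapered tube", L, r, r / sqrt(2), c_ref,
                               n_cells = max(8L, round(L / 0.02)),
                               rho = rho, P_ref = P_mean)
      build_network(list(v), junctions = list(),
                    terminals = list("1" = anechoic_terminal(v, rho, mean_flow, P_mean)),
                    root = 1L, aortic_path = 1L, name = "tapered_tube")
    },
    murray_tree = murray_tree_network(depth, rho, mean_flow, P_mean),
    single_reflector = {
      n1 <- max(8L, round(reflector_at / 0.0025))
      v1 <- vessel_from_targets(1L, "proximal line", reflector_at, r, r, 5,
                                n_cells = n1, rho = rho, P_ref = P_mean)
      # distal vessel: same lumen, stiffness raised so Z_c jumps by z_step
      Z1 <- reference_impedance(v1, rho, P_mean, x = v1$length)
      c2 <- uniroot(function(cc) {
        v <- vessel_from_targets(2L, "distal line", L, r, r, cc,
                                 n_cells = 8L, rho = rho, P_ref = P_mean)
        reference_impedance(v, rho, P_mean, x = 0) - z_step * Z1
      }, c(3, 30))$root
      v2 <- vessel_from_targets(2L, "distal line", L, r, r, c2,
                                n_cells = max(8L, round(L / 0.0025)),
                                rho = rho, P_ref = P_mean)
      build_network(list(v1, v2),
                    junctions = list(list(parent = 1L, daughters = 2L)),
                    terminals = list("2" = anechoic_terminal(v2, rho, mean_flow, P_mean)),
                    root = 1L, aortic_path = c(1L, 2L),
                    name = "single_reflector")
    },
    mini_aorta = mini_aorta_network(rho)
  )
}

# symmetric Murray-matched tree: radii follow Murray's law; per-level
# stiffness is solved so the parallel daughter impedance equals the
# parent impedance at the reference pressure (forward matching).
murray_tree_network <- function(depth, rho, mean_flow,
                                P_mean = mmHg_to_Pa(100)) {
  depth <- as.integer(depth)
  stopifnot(depth >= 1)
  r0 <- 0.008; c0 <- 5; L0 <- 0.1
  vessels <- list(); junctions <- list(); terminals <- list()
  make_level_vessel <- function(id, lvl, c_lvl) {
    r <- r0 * 2^(-lvl / 3)
    vessel_from_targets(id, sprintf("level %d vessel", lvl),
                        L0 * 2^(-lvl / 2), r, r, c_lvl,
                        n_cells = 4L, rho = rho, P_ref = P_mean)
  }
  c_lvl <- c0
  ids_at_level <- list(1L)
  vessels[[1]] <- make_level_vessel(1L, 0L, c0)
  next_id <- 2L
  for (lvl in seq_len(depth)) {
    parent_ids <- ids_at_level[[lvl]]
    Zp <- reference_impedance(vessels[[parent_ids[1]]], rho, P_mean)
    # solve daughter wave speed so that Zd/2 = Zp at P_mean
    rd <- r0 * 2^(-lvl / 3)
    cd <- uniroot(function(cc) {
      v <- vessel_from_targets(999L, "probe", L0, rd, rd, cc,
                               n_cells = 4L, rho = rho, P_ref = P_mean)
      reference_impedance(v, rho, P_mean) / 2 - Zp
    }, c(sqrt(P_mean / (2 * rho)) * 1.01, 60))$root
    new_ids <- integer(0)
    for (p in parent_ids) {
      d1 <- next_id; d2 <- next_id + 1L; next_id <- next_id + 2L
      vessels[[d1]] <- make_level_vessel(d1, lvl, cd)
      vessels[[d2]] <- make_level_vessel(d2, lvl, cd)
      junctions[[length(junctions) + 1L]] <-
        list(parent = p, daughters = c(d1, d2))
      new_ids <- c(new_ids, d1, d2)
    }
    ids_at_level[[lvl + 1L]] <- new_ids
  }
  leaf_ids <- ids_at_level[[depth + 1L]]
  leaf_flow <- mean_flow / length(leaf_ids)
  for (id in leaf_ids)
    terminals[[as.character(id)]] <-
      anechoic_terminal(vessels[[id]], rho, leaf_flow, P_mean)
  build_network(vessels, junctions, terminals, root = 1L,
                name = sprintf("murray_tree_depth%d", depth))
}

# Reduced 14-vessel adult arterial tree.  Radii and wave-speed targets
# are stated at 100 mmHg; aortic wave speeds follow the usual proximal
# (~3.9 m/s) to iliac (~5.1 m/s) gradient, carotid ~6.8 and tibial
# ~7.4 m/s.  Elevations are for the upright body, positive below heart
# level.  Terminals split a cardiac output of 87.5 ml/s as head 15%,
# arm 12%, legs 73% at a mean aortic pressure of 93 mmHg above an
# outflow pressure of 33.2 mmHg (the conventional Windkessel asymptote).
mini_aorta_network <- function(rho = 1050) {
  P_ref <- mmHg_to_Pa(100)
  spec <- list(
    #      id  name                  L     r_p    r_d    c     phi  group      cells
    list( 1L, "aortic root",        0.03, 0.0145, 0.0140, 3.85, -20, "aortic",   4L),
    list(63L, "ascending aorta",    0.03, 0.0140, 0.0135, 3.89, -20, "aortic",   6L),
    list( 2L, "aortic arch A",      0.04, 0.0135, 0.0125, 4.05, -20, "aortic",   4L),
    list(14L, "aortic arch B",      0.04, 0.0120, 0.0115, 4.24,  20, "aortic",   8L),
    list(18L, "thoracic aorta A",   0.06, 0.0110, 0.0100, 4.32,  75, "aortic",  10L),
    list(27L, "thoracic aorta B",   0.06, 0.0100, 0.0095, 4.45,  80, "aortic",   6L),
    list(28L, "abdominal aorta A",  0.06, 0.0095, 0.0090, 4.60,  85, "aortic",   6L),
    list(35L, "abdominal aorta B",  0.05, 0.0090, 0.0085, 4.70,  85, "aortic",   5L),
    list(37L, "abdominal aorta C",  0.05, 0.0085, 0.0080, 4.80,  85, "aortic",   5L),
    list(39L, "abdominal aorta D",  0.05, 0.0080, 0.0075, 4.85,  85, "aortic",  10L),
    list(41L, "iliac bifurcation",  0.09, 0.0075, 0.0065, 5.06,  80, "aortic",   4L),
    list(13L, "external carotid",   0.17, 0.0025, 0.0020, 6.77, -62, "cerebral", 10L),
    list(24L, "arm (interosseous)", 0.45, 0.0035, 0.0020, 6.00,  35, "limb",    16L),
    list(48L, "leg (tibial trunk)", 0.85, 0.0065, 0.0050, 7.42,  70, "limb",    24L)
  )
  # chain elevations along the aortic path, then hang the branches
  path <- c(1L, 63L, 2L, 14L, 18L, 27L, 28L, 35L, 37L, 39L, 41L)
  byid <- function(id) Filter(function(s) s[[1]] == id, spec)[[1]]
  z <- 0; z_prox <- c()
  for (id in path) {
    s <- byid(id)
    z_prox[as.character(id)] <- z
    z <- z + s[[3]] * sin(s[[7]] * pi / 180)
  }
  z_prox["13"] <- z_prox["14"]                      # off the arch
  z_prox["24"] <- z_prox["18"]                      # off the distal arch
  z_prox["48"] <- z + 0                              # off the iliac end
  # recompute: 48 hangs from the distal end of 41 (z after the loop)

  # Kelvin-Voigt wall damping, scaled with lumen size (mid-range values
  # for large human arteries); the elastic-only tube fixtures stay
  # undamped so their closed-form wave speed remains an exact oracle
  gamma_wall <- function(r_p, r_d) 150 * sqrt(pi * ((r_p + r_d) / 2)^2)
  vessels <- lapply(spec, function(s)
    vessel_from_targets(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]],
                        phi = s[[7]], z_prox = unname(z_prox[as.character(s[[1]])]),
                        group = s[[8]], n_cells = s[[9]],
                        rho = rho, P_ref = P_ref,
                        Gamma = gamma_wall(s[[4]], s[[5]])))
  names(vessels) <- vapply(spec, function(s) as.character(s[[1]]), "")

  junctions <- list(
    list(parent = 1L,  daughters = 63L),
    list(parent = 63L, daughters = 2L),
    list(parent = 2L,  daughters = c(14L, 13L)),
    list(parent = 14L, daughters = c(18L, 24L)),
    list(parent = 18L, daughters = 27L),
    list(parent = 27L, daughters = 28L),
    list(parent = 28L, daughters = 35L),
    list(parent = 35L, daughters = 37L),
    list(parent = 37L, daughters = 39L),
    list(parent = 39L, daughters = 41L),
    list(parent = 41L, daughters = 48L)
  )

  P_map <- mmHg_to_Pa(93); P_out <- mmHg_to_Pa(33.2)
  CO <- 70e-6 / 0.8
  R_total <- (P_map - P_out) / CO
  frac <- c("13" = 0.13, "24" = 0.12, "48" = 0.75)
  terminals <- list()
  for (id in names(frac)) {
    v <- vessels[[id]]
    R_down <- R_total / frac[[id]]
    R1 <- reference_impedance(v, rho, P_ref, x = v$length)
    if (R1 >= R_down)
      stop("terminal impedance exceeds downstream resistance at vessel ", id)
    R2 <- R_down - R1
    C <- frac[[id]] * 8e-9       # ~1.1 ml/mmHg of lumped peripheral compliance
    terminals[[id]] <- terminal_windkessel(R1, R2, C, P_out)
  }

  build_network(unname(vessels), junctions, terminals, root = 1L,
                aortic_path = path, name = "mini_aorta")
}

#' Default inflow pairing for a canonical network
#'
#' Returns the inflow waveform each bundled network was sized for:
#' 70 ml at 0.8 s for `mini_aorta`, a small 5 ml pulse for the tube and
#' tree fixtures (keeping them in the near-linear regime), and a short
#' 4 ml pulse for `single_reflector` so the echo is temporally isolated.
#'
#' @param name canonical network name.
#' @return a `pw_inflow`.
#' @export
canonical_inflow <- function(name) {
  name <- match.arg(name, c("uniform_tube", "tapered_tube", "murray_tree",
                            "mini_aorta", "single_reflector"))
  switch(name,
    mini_aorta = inflow_waveform(RR = 0.8, SV = 70e-6),
    single_reflector = inflow_waveform(RR = 0.8, SV = 0.5e-6,
                                       shape = "ramp",
                                       ejection_fraction = 0.04),
    inflow_waveform(RR = 0.8, SV = 5e-6))
}
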
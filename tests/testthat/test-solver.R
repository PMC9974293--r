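# 1D solver: rest states, hydrostatics, matched-tube propagation,
# junction coupling, Windkessel terminals, convergence checking.

test_that("zero inflow at zero tilt relaxes to the outflow pressure", {
  v <- vessel_from_targets(1L, "t", 0.4, 0.008, 0.008, 6, n_cells = 10L)
  P0 <- mmHg_to_Pa(60)
  tm <- terminal_windkessel(R1 = 1e7, R2 = 1e8, C = 0, P_out = P0)
  net <- build_network(list(v), list(), list("1" = tm), 1L)
  sim <- simulate_beats(net, inflow_waveform(RR = 0.5, SV = 1e-13),
                        posture = 0, sim = sim_config(max_beats = 10),
                        P_init = P0)
  s <- sim_series(sim, 1, 5)
  expect_lt(max(abs(s$P - P0)), 1)        # within 1 Pa
  expect_lt(max(abs(s$Q)), 1e-9)          # < 0.001 ml/s
})

test_that("hydrostatic equilibrium follows Stevino's law at any tilt", {
  # closed-form offsets
  expect_equal(hydrostatic_offset(0.5, 90, rho = 1050), 1050 * 9.81 * 0.5)
  expect_lt(abs(hydrostatic_offset(0.5, 90, 1050) - mmHg_to_Pa(38.6)) /
              mmHg_to_Pa(38.6), 0.01)
  expect_equal(hydrostatic_offset(0.7, 0), 0)
  expect_equal(hydrostatic_offset(0.5, 30), hydrostatic_offset(0.5, 90) / 2)

  # simulated rest state at 90 degrees on the anatomical tree
  net <- canonical_network("mini_aorta")
  P0 <- mmHg_to_Pa(33.2)
  sim <- simulate_beats(net, inflow_waveform(RR = 0.5, SV = 1e-13),
                        posture = 90, sim = sim_config(max_beats = 8),
                        P_init = P0)
  root <- sim_series(sim, 1, 1)
  for (probe in list(c(48, 24), c(13, 10), c(41, 4))) {
    s <- sim_series(sim, probe[1], probe[2])
    expected <- 1050 * 9.81 * (s$z - root$z)
    expect_lt(abs((mean(s$P) - mean(root$P)) - expected),
              0.01 * abs(expected) + 40)
  }
})

test_that("a matched tube is reflection-free and carries waves at the tube-law speed", {
  sim <- matched_tube_sim()
  net <- sim$network
  v <- net$vessels[["1"]]
  s <- sim_series(sim, 1, 25)
  zc <- estimate_zc_pq(s)
  cpu <- estimate_c_pu(s)
  sep <- separate_waves(s, zc)
  wi <- compute_wi(s, cpu)

  # backward pulse amplitude < 1% of forward
  expect_lt(sep$PP_b / sep$PP_f, 0.01)
  # backward energy < 1% of forward
  expect_lt(trapz_uniform(wi$t, abs(wi$WI_b)) / trapz_uniform(wi$t, wi$WI_f),
            0.01)
  # PU-loop speed within 2% of the analytic tube-law speed at beat-mean A
  c_wall <- wave_speed(mean(s$A), v, 1050, x = s$x)
  expect_rel(cpu$c, c_wall, 0.02)
  # impedance identity Zc A / (rho c) = 1 within 5%
  expect_lt(abs(zc$Zc * mean(s$A) / (1050 * cpu$c) - 1), 0.05)

  # foot-to-foot transit time along the tube within 3% of L / c
  first <- sim_series(sim, 1, 1)
  last <- sim_series(sim, 1, v$n_cells)
  foot_t <- function(s) {
    lm_ <- beat_landmarks(s$P)
    s$t[lm_$i_foot]
  }
  dt_ff <- foot_t(last) - foot_t(first)
  expect_rel(dt_ff, (last$x - first$x) / c_wall, 0.03)
})

test_that("grid refinement changes the beat peak by under 1%", {
  peak_at_mid <- function(n_cells) {
    v <- vessel_from_targets(1L, "t", 1.0, 0.01, 0.01, 8,
                             n_cells = n_cells)
    Zc <- reference_impedance(v, 1050, mmHg_to_Pa(100), x = 1)
    tm <- terminal_windkessel(R1 = Zc, R2 = 0, C = 0,
                              P_out = mmHg_to_Pa(100) - 6.25e-6 * Zc)
    net <- build_network(list(v), list(), list("1" = tm), 1L)
    sim <- simulate_beats(net, inflow_waveform(RR = 0.8, SV = 5e-6),
                          posture = 0,
                          sim = sim_config(max_beats = 15,
                                           friction_coefficient = 0))
    max(sim_series(sim, 1, n_cells %/% 2)$P)
  }
  expect_rel(peak_at_mid(100L), peak_at_mid(50L), 0.01)
})

test_that("junction matching conserves mass and total pressure", {
  b <- 2 * 1050 * 36    # tube-law b for c0 = 6 m/s at A = A0
  A0 <- 1e-4
  beta <- b * sqrt(A0)
  c0 <- sqrt(beta / (2 * 1050 * A0)) * A0^0.25

  # continuation of identical vessels: small incident forward wave is
  # transmitted essentially unchanged
  dU <- 0.01
  rc <- 1050 * c0
  # incident forward wave: dP = rho c dU, dA from dP
  dA <- 2 * A0 * (1050 * c0 * dU) / b   # dP/dA ~ b/(2A0) at A = A0
  Wp <- (dU) + 4 * wave_speed(A0 + dA,
                              vessel_segment(9L, length = 1, A0_prox = A0,
                                             beta = beta, n_cells = 2L))
  res <- junction_match(list(beta = beta, A0 = A0, W = Wp),
                        list(list(beta = beta, A0 = A0, W = -4 * c0)))
  expect_lt(res$mass_residual, 1e-10)
  dP_in <- rc * dU
  expect_lt(abs(res$P_daughters[1] / dP_in - 1), 0.005)  # transmitted
  # reflected amplitude at the parent below 0.5% of incident
  expect_lt(abs(res$P_parent - res$P_daughters[1]) / dP_in, 0.005)

  # impedance-matched bifurcation (Zd = 2 Zp each): near-zero reflection,
  # consistent with the forward reflection-coefficient formula
  vset <- canonical_network("murray_tree", depth = 1L)
  pv <- vset$vessels[[1]]; dv <- vset$vessels[[2]]
  cp0 <- wave_speed(pv$A0_prox, pv)
  cd0 <- wave_speed(dv$A0_prox, dv)
  res2 <- junction_match(
    list(beta = pv$beta, A0 = pv$A0_prox, W = 0.01 + 4 * cp0),
    list(list(beta = dv$beta, A0 = dv$A0_prox, W = -4 * cd0),
         list(beta = dv$beta, A0 = dv$A0_prox, W = -4 * cd0)))
  expect_lt(res2$mass_residual, 1e-10)
  # parent and daughter pressure excursions nearly equal (R_p ~ 0)
  expect_lt(abs(res2$P_parent - res2$P_daughters[1]) /
              max(abs(res2$P_parent), 1), 0.02)
})

test_that("terminal Windkessel reproduces its DC limit and closed-end doubling", {
  # steady flow: P - P_out -> Q (R1 + R2)
  v <- vessel_from_targets(1L, "t", 0.1, 0.01, 0.01, 6, n_cells = 4L)
  q0 <- 5e-6
  tm <- terminal_windkessel(R1 = 2e7, R2 = 3e8, C = 4e-9,
                            P_out = mmHg_to_Pa(10))
  net <- build_network(list(v), list(), list("1" = tm), 1L)
  sim <- simulate_beats(net, constant_inflow(q0), posture = 0,
                        sim = sim_config(max_beats = 30,
                                         convergence_tol = 1e-6))
  s <- sim_series(sim, 1, 4)
  expect_rel(mean(s$P) - tm$P_out, q0 * (tm$R1 + tm$R2), 0.01)

  # closed end (R2 huge): incident pulse reflects with ~doubled pressure
  vclose <- vessel_from_targets(1L, "t", 1.0, 0.01, 0.01, 8, n_cells = 50L)
  tmc <- terminal_windkessel(R1 = 0, R2 = 1e15, C = 0,
                             P_out = mmHg_to_Pa(100))
  netc <- build_network(list(vclose), list(), list("1" = tmc), 1L)
  # one small pulse launched from rest; a sealed tube stores every
  # ejected volume, so only the first beat is physically meaningful
  simc <- suppressWarnings(
    simulate_beats(netc, inflow_waveform(RR = 1.2, SV = 1e-6,
                                         ejection_fraction = 0.05),
                   posture = 0,
                   sim = sim_config(max_beats = 1,
                                    friction_coefficient = 0),
                   P_init = mmHg_to_Pa(100)))
  near <- sim_series(simc, 1, 2)
  far <- sim_series(simc, 1, 50)
  inc <- max(near$P[near$t < 0.1]) - near$P[1]
  refl <- max(far$P) - far$P[1]
  expect_lt(abs(refl / (2 * inc) - 1), 0.05)
})

test_that("periodic convergence checker handles canonical fixtures", {
  beat <- sin(seq(0, 2 * pi, length.out = 100))
  same <- check_periodic_convergence(list(beat, beat), tol = 1e-3)
  expect_true(same$converged)
  expect_equal(same$beat_change, 0)

  # geometric decay of the beat-to-beat change -> converged at beat 4
  beats <- list(beat)
  for (d in c(0.1, 0.01, 9e-4))
    beats[[length(beats) + 1]] <- beats[[length(beats)]] * (1 + d)
  geo <- check_periodic_convergence(beats, tol = 1e-3)
  expect_true(geo$converged)
  expect_equal(geo$beats_run, 4)
  expect_equal(geo$beat_change, c(0.1, 0.01, 9e-4), tolerance = 1e-9)

  osc <- check_periodic_convergence(list(beat, -beat, beat, -beat),
                                    tol = 1e-3)
  expect_false(osc$converged)
})

test_that("junction mass conservation holds to 1e-10 through a full run", {
  sims <- mini_sims()
  expect_lt(sims$sup$convergence$max_junction_residual, 1e-10)
  expect_lt(sims$std$convergence$max_junction_residual, 1e-10)
})
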
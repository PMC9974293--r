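# Wave intensity, wavefront classification, backward arrival time,
# downstream mean speed and the trapping (ToR/PoR) table.

test_that("wave intensity obeys the sign structure and pointwise identity", {
  set.seed(11)
  t <- seq(0, 0.8, length.out = 801)[-801]
  P <- mmHg_to_Pa(90) + 2000 * sin(2 * pi * t / 0.8) +
    500 * sin(6 * pi * t / 0.8 + 1)
  A <- 1e-4 * (1 + 0.05 * sin(2 * pi * t / 0.8 + 0.4))
  Q <- 5e-5 * (0.5 + 0.5 * sin(2 * pi * t / 0.8 - 0.3))
  s <- hemo_series(t, P, Q, A, RR = 0.8)
  wi <- compute_wi(s, c = 5)
  expect_true(all(wi$WI_f >= 0))
  expect_true(all(wi$WI_b <= 0))
  resid <- wi$WI_f + wi$WI_b - wi$dPdt * wi$dUdt
  expect_lt(max(abs(resid)), 1e-10 * max(abs(wi$dPdt * wi$dUdt)))
})

test_that("a pure forward wave has no backward intensity", {
  rho <- 1050; c <- 5
  t <- seq(0, 0.8, length.out = 801)[-801]
  U <- 0.3 * exp(-((t - 0.2) / 0.05)^2)
  P <- mmHg_to_Pa(80) + rho * c * U
  A <- rep(1e-4, length(t))
  s <- hemo_series(t, P, U * 1e-4, A, RR = 0.8)
  wi <- compute_wi(s, c, rho)
  expect_lt(max(abs(wi$WI_b)), 1e-16 * max(wi$WI_f))
  expect_equal(wi$WI_f, wi$dPdt^2 / (rho * c), tolerance = 1e-10)
})

test_that("wavefront classification labels compression and decompression", {
  rho <- 1050; c <- 5
  t <- seq(0, 0.8, length.out = 1601)[-1601]
  # forward Gaussian upstroke then (later) downstroke of a plateau pulse
  U <- 0.3 * (pnorm(t, 0.15, 0.02) - pnorm(t, 0.45, 0.02))
  P <- mmHg_to_Pa(80) + rho * c * U
  s <- hemo_series(t, P, U * 1e-4, rep(1e-4, length(t)), RR = 0.8)
  wi <- compute_wi(s, c, rho)
  sep <- separate_waves(s, rho * c / 1e-4)
  pk <- classify_wavefronts(wi, sep, prominence = 0.02)
  expect_equal(pk$label, c("FCW", "FDW"))
  expect_lt(abs(pk$time[1] - 0.15), 0.01)
  expect_lt(abs(pk$time[2] - 0.45), 0.01)

  # nothing above threshold -> empty frame, not an error
  flat <- hemo_series(t, rep(mmHg_to_Pa(80), length(t)),
                      rep(0, length(t)), rep(1e-4, length(t)), RR = 0.8)
  wif <- compute_wi(flat, c, rho)
  expect_equal(nrow(classify_wavefronts(wif, separate_waves(flat, 1e7))), 0)
})

test_that("closed-end reflection returns as a backward compression wave", {
  # near-closed termination (reflection coefficient ~0.95); friction on
  # so the cavity reaches a periodic state
  v <- vessel_from_targets(1L, "t", 1.0, 0.01, 0.01, 8, n_cells = 50L)
  tm <- terminal_windkessel(R1 = 0, R2 = 1e9, C = 0,
                            P_out = mmHg_to_Pa(100))
  net <- build_network(list(v), list(), list("1" = tm), 1L)
  sim <- suppressWarnings(
    simulate_beats(net, inflow_waveform(RR = 1.2, SV = 1e-6,
                                        ejection_fraction = 0.05),
                   posture = 0,
                   sim = sim_config(max_beats = 40),
                   P_init = mmHg_to_Pa(100)))
  s <- sim_series(sim, 1, 25)
  wi <- compute_wi(s, estimate_c_pu(s))
  sep <- separate_waves(s, estimate_zc_pq(s))
  pk <- classify_wavefronts(wi, sep, prominence = 0.05)
  t_fcw <- pk$time[pk$label == "FCW"][1]
  # first backward wavefront following the ejection is the echo off the
  # near-closed end: a compression
  bcw <- pk[pk$direction == "backward" & pk$time > t_fcw, ]
  expect_gt(nrow(bcw), 0)
  expect_equal(bcw$type[1], "compression")
})

test_that("backward arrival time is the intensity-weighted mean", {
  expect_equal(backward_arrival_time(make_wi_fixture(0.3)), 0.3,
               tolerance = 1e-3)
  expect_equal(backward_arrival_time(make_wi_fixture(c(0.2, 0.4))), 0.3,
               tolerance = 1e-3)
  expect_equal(backward_arrival_time(
    make_wi_fixture(c(0.2, 0.5), weights = c(2, 1))), 0.3, tolerance = 1e-3)
  empty <- make_wi_fixture(0.3)
  empty$WI_b[] <- 0
  expect_error(backward_arrival_time(empty), "undefined")
})

test_that("mean downstream speed uses the inclusive convention", {
  cs <- c(4, 6)
  expect_equal(mean_downstream_speed(cs, 1), 5)
  expect_equal(mean_downstream_speed(cs, 2), 6)     # last site = local c
  expect_equal(mean_downstream_speed(rep(5.2, 7), 3), 5.2)
  expect_equal(mean_downstream_speed(c(4, 6), 1, inclusive = FALSE), 6)
})

test_that("the echo fixture localizes the reflector within 5%", {
  sim <- reflector_sim()
  sim$network$aortic_path <- 1L
  # near-inlet site so the echo path spans almost the whole proximal line
  v <- sim$network$vessels[["1"]]
  s <- sim_series(sim, 1, 3)
  cpu <- estimate_c_pu(s)
  wi <- compute_wi(s, cpu)
  sep <- separate_waves(s, estimate_zc_pq(s))
  pk <- classify_wavefronts(wi, sep, 0.02)
  fcw <- pk[pk$label == "FCW" & pk$intensity >= 0.5 * max(wi$WI_f), ]
  tor <- backward_arrival_time(wi) - fcw$time[1]
  por <- tor * cpu$c / 2
  expect_rel(por, 0.4 - s$x, 0.05)
})

test_that("FCW arrivals move causally down the aorta", {
  sims <- mini_sims()
  tr <- reflection_horizon(sims$sup)
  expect_true(all(diff(tr$t_fcw_s) > 0))
  expect_true(all(is.finite(tr$por_m)))
})

test_that("FCW arrival slope matches the wave speed on a clean line", {
  # interference-free fixture: peak arrival timing is only meaningful
  # where junction reflections do not reshape the wavefront
  sim <- matched_tube_sim()
  v <- sim$network$vessels[["1"]]
  cells <- seq(5L, 45L, by = 5L)
  rows <- lapply(cells, function(e) {
    s <- sim_series(sim, 1, e)
    wi <- compute_wi(s, estimate_c_pu(s))
    sep <- separate_waves(s, estimate_zc_pq(s))
    pk <- classify_wavefronts(wi, sep, 0.02)
    fcw <- pk[pk$label == "FCW" & pk$intensity >= 0.5 * max(wi$WI_f), ]
    data.frame(distance = s$x, time = fcw$time[1], c = s$x * 0 +
                 wave_speed(mean(s$A), v, 1050, x = s$x))
  })
  tab <- do.call(rbind, rows)
  slope <- unname(stats::coef(stats::lm(time ~ distance, tab))[2])
  expect_rel(slope, 1 / mean(tab$c), 0.15)
})
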
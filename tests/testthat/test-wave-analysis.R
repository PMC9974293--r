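# PQ/PU loop estimators, wave separation, reflection indices,
# augmentation index, reflection coefficients, input impedance.

synthetic_beat <- function(Z = 1e7, P0 = mmHg_to_Pa(80), RR = 0.8,
                           n = 800L, bump = 0) {
  t <- seq(0, RR, length.out = n + 1L)[-(n + 1L)]
  Q <- ifelse(t <= 0.3, sin(pi * t / 0.3)^2, 0) * 1e-4
  P <- P0 + Z * Q
  if (bump > 0)                      # late-systolic reflected bump
    P <- P + bump * exp(-((t - 0.26) / 0.03)^2)
  hemo_series(t, P, Q, A = rep(5e-5, n), RR = RR)
}

test_that("PQ-loop recovers an exact resistive relation", {
  s <- synthetic_beat(Z = 1e7)
  fit <- estimate_zc_pq(s)
  expect_rel(fit$Zc, 1e7, 1e-6)
  expect_gt(fit$r2, 0.999)
  expect_false(fit$flagged)
})

test_that("PQ-loop stays within 5% under a late-systolic reflected bump", {
  s <- synthetic_beat(Z = 1e7, bump = mmHg_to_Pa(10))
  fit <- estimate_zc_pq(s)
  expect_rel(fit$Zc, 1e7, 0.05)
})

test_that("degenerate flat signals raise estimation errors", {
  t <- seq(0, 0.8, length.out = 801)[-801]
  P <- mmHg_to_Pa(80) + 1000 * sin(2 * pi * t / 0.8)
  s <- hemo_series(t, P, Q = rep(1e-5, 800), RR = 0.8)
  expect_error(estimate_zc_pq(s), "flat flow")
})

test_that("PU-loop recovers an exact wave speed", {
  rho <- 1050
  t <- seq(0, 0.8, length.out = 801)[-801]
  A <- rep(1e-4, 800)
  Q <- ifelse(t <= 0.3, sin(pi * t / 0.3)^2, 0) * 2e-5
  U <- Q / A
  P <- mmHg_to_Pa(70) + rho * 5 * U
  s <- hemo_series(t, P, Q, A, RR = 0.8)
  fit <- estimate_c_pu(s, rho)
  expect_rel(fit$c, 5, 1e-6)
})

test_that("wave separation obeys its algebra and reconstruction identities", {
  # pure forward: P = Zc Q
  s <- synthetic_beat(Z = 1e7, P0 = 0)
  sep <- separate_waves(s, 1e7)
  expect_lt(max(abs(sep$P_b)), 1e-10 * max(abs(sep$P_f)))
  expect_lt(max(abs(sep$Q_b)), 1e-10 * max(abs(sep$Q_f)))

  # blocked line: constant 100 mmHg, no flow -> both components 50 mmHg
  t <- seq(0, 0.8, length.out = 101)[-101]
  sblock <- hemo_series(t, rep(mmHg_to_Pa(100), 100), rep(0, 100), RR = 0.8)
  sepb <- separate_waves(sblock, 1e7)
  expect_equal(unique(sepb$P_f), mmHg_to_Pa(50))
  expect_equal(unique(sepb$P_b), mmHg_to_Pa(50))

  # synthesis-then-analysis round trip to 1e-10
  fix <- make_superposed_waves()
  sep2 <- separate_waves(fix$series, fix$Zc)
  expect_lt(max(abs(sep2$P_f - fix$P_f)), 1e-10 * max(abs(fix$P_f)))
  expect_lt(max(abs(sep2$P_b - fix$P_b)), 1e-10 * max(abs(fix$P_f)))

  # reconstruction identity on an arbitrary series
  s3 <- synthetic_beat(bump = mmHg_to_Pa(7))
  sep3 <- separate_waves(s3, 8e6)
  expect_lt(max(abs(sep3$P_f + sep3$P_b - s3$P)), 1e-10 * max(abs(s3$P)))
  expect_lt(max(abs(sep3$Q_f + sep3$Q_b - s3$Q)), 1e-10 * max(abs(s3$Q)))
})

test_that("reflection magnitude recovers constructed amplitude ratios", {
  fix <- make_superposed_waves(
    forward = list(amp = mmHg_to_Pa(20), t0 = 0.2, width = 0.04),
    backward = list(amp = mmHg_to_Pa(8), t0 = 0.5, width = 0.04))
  sep <- separate_waves(fix$series, fix$Zc)
  refl <- vessel_reflection_indices(list(sep))
  expect_rel(refl$RM, 8 / 20, 1e-6)
  # swapping the components inverts the ratio
  fix2 <- make_superposed_waves(
    forward = list(amp = mmHg_to_Pa(8), t0 = 0.5, width = 0.04),
    backward = list(amp = mmHg_to_Pa(20), t0 = 0.2, width = 0.04))
  sep2 <- separate_waves(fix2$series, fix2$Zc)
  expect_rel(vessel_reflection_indices(list(sep2))$RM, 20 / 8, 1e-6)
})

test_that("RI equals RM / (1 + RM) and zero-reflection degenerates cleanly", {
  set.seed(7)
  for (k in 1:20) {
    sep <- list(structure(list(PP_f = runif(1, 500, 6000),
                               PP_b = runif(1, 0, 4000)),
                          class = "pw_separation"))
    refl <- vessel_reflection_indices(sep)
    expect_equal(refl$RI, refl$RM / (1 + refl$RM), tolerance = 1e-12)
  }
  none <- vessel_reflection_indices(
    list(structure(list(PP_f = 1000, PP_b = 0), class = "pw_separation")))
  expect_equal(none$RM, 0)
  expect_equal(none$RI, 0)
  expect_error(vessel_reflection_indices(
    list(structure(list(PP_f = 0, PP_b = 0), class = "pw_separation"))),
    "PP_f")
})

test_that("augmentation index finds shoulders with the right sign", {
  t <- seq(0, 0.8, length.out = 1001)[-1001]
  base <- mmHg_to_Pa(80)
  main <- function(t0) mmHg_to_Pa(30) * exp(-((t - t0) / 0.06)^2)
  shoulder <- function(t0) mmHg_to_Pa(12) * exp(-((t - t0) / 0.045)^2)

  # shoulder before the peak: positive AP close to the constructed offset
  Ppos <- base + main(0.25) + shoulder(0.13)
  spos <- hemo_series(t, Ppos, Q = sin(2 * pi * t / 0.8) * 1e-5, RR = 0.8)
  aip <- augmentation_index(spos)
  expect_false(aip$flagged)
  expect_gt(aip$AI, 0)
  expect_lt(aip$t_inflection, aip$t_sys)
  # AP should be near P_sys - P(shoulder inflection); loose bound: within
  # 40% of the shoulder amplitude
  expect_lt(abs(aip$AP - (max(Ppos) - Ppos[which.min(abs(t - 0.175))])),
            0.4 * mmHg_to_Pa(12))

  # inflection after the peak: negative AI
  Pneg <- base + main(0.18) + shoulder(0.38)
  sneg <- hemo_series(t, Pneg, Q = sin(2 * pi * t / 0.8) * 1e-5, RR = 0.8)
  ain <- augmentation_index(sneg)
  expect_false(ain$flagged)
  expect_lt(ain$AI, 0)
  expect_gt(ain$t_inflection, ain$t_sys)

  # single smooth pulse: no inflection, flagged, AI undefined
  Pone <- base + main(0.25)
  sone <- hemo_series(t, Pone, Q = sin(2 * pi * t / 0.8) * 1e-5, RR = 0.8)
  aio <- augmentation_index(sone)
  expect_true(aio$flagged)
  expect_true(is.na(aio$AI))
})

test_that("reflection coefficients match their closed-form examples", {
  # forward bifurcation: parent 1, daughters 3 and 6 in parallel -> 1/3
  expect_equal(rp_bifurcation(1, c(3, 6), "forward")$value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(rp_bifurcation(1, c(2, 2), "forward")$value, 0,
               tolerance = 1e-12)
  # matched-forward symmetric bifurcation: backward magnitude 0.5
  expect_equal(rp_bifurcation(1, c(2, 2), "backward")$value, 0.5,
               tolerance = 1e-12)
  # backward on a continuation reduces to the two-vessel mismatch
  cont <- rp_bifurcation(1, 3, "backward")
  expect_equal(cont$value, abs((1 - 3) / (1 + 3)), tolerance = 1e-12)

  # taper telescoping
  expect_equal(rp_taper(c(1, 1, 1))$value, 0)
  expect_equal(rp_taper(c(1, 3))$value, 0.5)
  expect_equal(rp_taper(c(1, 2, 4))$value, 2 / 3, tolerance = 1e-12)

  # terminal limits
  expect_equal(rp_terminal(5e8, 5e8)$value, 0)
  expect_equal(rp_terminal(Inf, 5e8)$value, 1)
  expect_equal(rp_terminal(3, 1)$value, 0.5)
})

test_that("input impedance reproduces a resistive line and Windkessel limits", {
  s <- synthetic_beat(Z = 2e7, P0 = mmHg_to_Pa(40))
  zin <- input_impedance(s, P_reference = mmHg_to_Pa(40))
  ok <- !is.na(zin$modulus)
  expect_true(all(abs(zin$modulus[ok] / 2e7 - 1) < 1e-6))
  expect_true(all(abs(zin$phase[ok]) < 1e-6))

  sim <- windkessel_sim()
  tm <- sim$network$terminals[["1"]]
  s1 <- sim_series(sim, 1, 1)
  zin1 <- input_impedance(s1, P_reference = tm$P_out)
  # DC limit: Z_in(0) ~ R_down (small viscous drop along the short tube)
  expect_rel(zin1$modulus[1], tm$R_down, 0.01)
  # reflection-less high-frequency plateau near the PQ-loop Z_c; weight
  # harmonics by their flow content (spectral nulls of the inflow carry
  # no impedance information)
  zc <- estimate_zc_pq(s1)$Zc
  qh <- Mod(stats::fft(s1$Q))[8:13]
  hi <- zin1$modulus[8:13]
  ok <- !is.na(hi)
  expect_lt(abs(sum(hi[ok] * qh[ok]) / sum(qh[ok]) / zc - 1), 0.2)
})
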
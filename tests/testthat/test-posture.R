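# Head-up tilt transform: presets, factor application, TPR bisection.

test_that("supine preset is the identity", {
  net <- canonical_network("mini_aorta")
  inf <- canonical_inflow("mini_aorta")
  out <- apply_posture(net, inf, posture_state("supine"))
  expect_identical(out$network, net)
  expect_identical(out$inflow, inf)
  expect_equal(out$f_R, 1)
})

test_that("standing preset applies the tabulated set-point factors", {
  net <- canonical_network("mini_aorta")
  inf <- canonical_inflow("mini_aorta")
  out <- suppressMessages(apply_posture(net, inf, posture_state("standing")))
  expect_rel(out$inflow$RR, inf$RR / 1.23, 1e-12)
  expect_rel(out$inflow$SV, 0.68 * inf$SV, 1e-12)
  # cerebral terminal scaled by f_Rc / f_Cc
  expect_rel(out$network$terminals[["13"]]$R_down,
             0.88 * net$terminals[["13"]]$R_down, 1e-12)
  expect_rel(out$network$terminals[["13"]]$C,
             1.65 * net$terminals[["13"]]$C, 1e-12)
  # non-cerebral compliance x0.75
  expect_rel(out$network$terminals[["48"]]$C,
             0.75 * net$terminals[["48"]]$C, 1e-12)
  # total peripheral resistance raised by exactly +39% (0.1% tolerance)
  expect_rel(total_peripheral_resistance(out$network) /
               total_peripheral_resistance(net), 1.39, 1e-3)
})

test_that("inverting the applied factors restores the supine network", {
  net <- canonical_network("mini_aorta")
  inf <- canonical_inflow("mini_aorta")
  p <- posture_state("standing")
  out <- suppressMessages(apply_posture(net, inf, p))
  back <- out$network
  for (id in names(back$terminals)) {
    tm <- back$terminals[[id]]
    cere <- back$vessels[[id]]$group == "cerebral"
    fr <- if (cere) p$f_Rc else out$f_R
    fc <- if (cere) p$f_Cc else p$f_Cv
    back$terminals[[id]] <- terminal_windkessel(tm$R1 / fr, tm$R2 / fr,
                                                tm$C / fc, tm$P_out)
  }
  for (id in names(net$terminals)) {
    expect_rel(back$terminals[[id]]$R_down, net$terminals[[id]]$R_down, 1e-12)
    expect_rel(back$terminals[[id]]$C, net$terminals[[id]]$C, 1e-12)
  }
  inf_back <- rescale_inflow(out$inflow, f_HR = 1 / p$f_HR,
                             f_SV = 1 / p$f_SV)
  expect_rel(inf_back$RR, inf$RR, 1e-12)
  expect_rel(inf_back$SV, inf$SV, 1e-12)
})

test_that("cardiac output factor is consistent with the tabulated -15%", {
  p <- posture_state("standing")
  expect_lt(abs(p$f_HR * p$f_SV - 0.85), 0.02)
})

test_that("posture transform errors on impossible configurations", {
  # no cerebral terminals but f_Rc != 1
  tube <- canonical_network("uniform_tube")
  expect_error(suppressMessages(
    apply_posture(tube, canonical_inflow("uniform_tube"),
                  posture_state("standing"))),
    "no cerebral")
  # unreachable TPR: cerebral conductance alone exceeds the target
  net <- canonical_network("mini_aorta")
  p <- posture_state("custom", theta = 90, f_TPR = 25, f_Rc = 0.88)
  expect_error(suppressMessages(
    apply_posture(net, canonical_inflow("mini_aorta"), p)),
    "unreachable")
})
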
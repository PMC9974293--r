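# pulsewave

Arterial pressure–flow waves carry the mechanical fingerprint of the
circulation: they leave the heart, cross bifurcations and tapering
vessels, reflect off the peripheral microvasculature, and return as
backward waves.  In the supine body this system is strikingly well
organized — forward waves pass bifurcations almost without loss, while
reflected waves are re-reflected and trapped before they can reach the
heart.  `pulsewave` is an R package for asking, quantitatively, what
happens to this organization when the body stands up.

It provides, in one tested toolchain:

* a **1D arterial-network pulse-wave simulator** (nonlinear elastic /
  visco-elastic tube law, gravity via hydrostatic loading, RCR
  Windkessel terminals, explicit Lax–Wendroff core in C++ with
  characteristic junction coupling);
* a **head-up tilt transform** applying the steady-state haemodynamic
  shifts of passive tilt (heart rate +23%, stroke volume −32%, total
  peripheral resistance +39%, cerebral resistance −12%, cerebral
  compliance +65%, peripheral compliance −25%) plus the 90° hydrostatic
  field;
* a **wave-analysis toolkit**: wave separation
  `P_f,b = (P ± Z_c Q)/2` from PQ-loop characteristic impedance,
  PU-loop wave speed (slope `ρc`), reflection magnitude
  `RM = PP_b/PP_f`, reflection index `RI = PP_b/(PP_f+PP_b)`,
  augmentation index `AI = AP/PP`, reflection coefficients
  `R_p = (Z_d − Z_p)/(Z_d + Z_p)` at bifurcations, telescoped taper
  sums, terminal `R_p = (R_down − Z_c)/(R_down + Z_c)`, and input
  impedance spectra;
* **wave-intensity analysis**: `WI_f,b = ±(dP/dt ± ρc dU/dt)²/(4ρc)`,
  wavefront classification (FCW/FDW/BCW/BDW), and the moving-horizon
  procedure: time of reflection `ToR = t_back − t_FCW` with
  `t_back = ∫ t·WI_b dt / ∫ WI_b dt`, and point of reflection
  `PoR = ToR·c̄_down/2` along the aorta;
* the matching **statistics**: exact paired Wilcoxon signed-rank tests
  and ANCOVA comparison of arrival-time regression lines.

Everything runs on bundled, code-generated networks (a reflection-free
tube, a Murray-matched tree, a single-reflector echo fixture, and a
14-vessel reduced adult "mini aorta"), or on externally supplied
pressure/flow tables.

## Worked example

```r
library(pulsewave)

net <- canonical_network("mini_aorta")
net
#> <pw_network> mini_aorta
#>   vessels:   14
#>   junctions: 11 (2 bifurcations)
#>   terminals: 3
#>   root:      1
#>   aortic path: 1 > 63 > 2 > 14 > 18 > 27 > 28 > 35 > 37 > 39 > 41

inf <- canonical_inflow("mini_aorta")   # 70 ml at RR = 0.8 s
sup <- simulate_beats(net, inf, posture_state("supine"))
sup
#> <pw_sim> mini_aorta at tilt 0 deg
#> <pw_convergence> beats=7 converged=TRUE last_change=0.000801 (tol 0.001)
#>  max junction mass residual: 1e-10

std <- simulate_beats(net, inf, posture_state("standing"))
cmp <- compare_posture(wave_analysis_report(sup), wave_analysis_report(std))
cmp[cmp$vessel_id %in% c(63, 18, 41, 13, 48),
    c("name", "n", "c_supine", "c_standing", "delta_c_pct", "p_c",
      "RM_supine", "RM_standing")]
#>                name  n c_supine c_standing delta_c_pct      p_c RM_supine RM_standing
#>     ascending aorta  6     5.65       5.78        2.38 3.13e-02     0.451      0.3748
#>    thoracic aorta A 10     5.29       5.79        9.27 1.95e-03     0.451      0.4228
#>   iliac bifurcation  4     7.76       9.36       20.63 1.25e-01     0.303      0.4062
#>    external carotid 10    10.72       9.78       -8.78 1.95e-03     0.111      0.0992
#>  leg (tibial trunk) 24     8.17       9.31       13.88 8.34e-06     0.209      0.3618
```

Reading this: each vessel's PU-loop wave speed `c` is averaged over its
`n` discretized segments, and the paired Wilcoxon p-value (`p_c`)
compares segments between postures — note the exact minimal p at the
4-segment iliac site.  Standing raises `c` at every below-heart aortic
and leg site (hydrostatic distension stiffens the nonlinear wall) and
lowers it at the carotid, where cerebral vasodilation and the negative
hydrostatic column reduce distending pressure.  The reflection
magnitude at the ascending aorta *falls* on standing — reflections are
not amplified by the stiffer standing tree.

The trapping table localizes where backward waves appear to come from:

```r
head(reflection_horizon(sup), 3)
#> Aortic wave-trapping table (ToR/PoR):
#>  site_id distance_m t_fcw_s t_back_s  tor_s c_m_s c_down_m_s  por_m
#>        1    0.01125   0.001   0.2511 0.2501 5.223      5.854 0.7321
#>       63    0.04250   0.011   0.2889 0.2779 5.638      5.917 0.8222
#>        2    0.07500   0.019   0.3069 0.2879 5.817      5.948 0.8563
```

A command-line front end (`inst/exec/pulsewave`, a thin wrapper over
`pipeline_main()`) exposes `simulate`, `analyze`, `wia`, `trapping`,
`compare-posture` and `fixtures` subcommands operating on network JSON
and waveform CSV files.

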
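---
title: "Arterial pulse-wave simulation and wave analysis under postural change: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial pulse-wave simulation and wave analysis under postural change: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`pulsewave` simulates one converged heartbeat of blood pressure and flow
on a one-dimensional arterial tree, transforms that tree from the supine
to the standing posture, and analyses the resulting pulse waves with the
standard toolkit of arterial wave mechanics: forward/backward wave
separation, characteristic-impedance and wave-speed estimation from
PQ-/PU-loops, reflection indices (RM, RI, AI), reflection coefficients
at bifurcations, tapers and terminal beds, input-impedance spectra,
wave-intensity analysis (WIA), and the "moving horizon" time/point of
reflection (ToR/PoR) along the aorta.

The scientific question this serves: the supine arterial tree is
near-optimal for wave transport — forward waves cross bifurcations with
little reflection while backward waves are trapped — and the package
lets one ask, in a controlled in-silico setting, whether that
organization survives passive head-up tilt.

## Governing equations

Each vessel carries the 1D mass and momentum balance on area `A(x,t)`
and flow `Q(x,t)`:

```
A_t + Q_x = 0
Q_t + (alpha Q^2/A)_x + (A/rho) P_x = -K_R Q/A + A g sin(theta) sin(phi)
```

with blood density `rho = 1050 kg/m^3`, viscosity `mu = 0.004 Pa s`, a
flat-profile momentum correction `alpha = 1`, and a Womersley-motivated
friction source `K_R = 22 pi mu / rho`.  Gravity enters as a body force
set by the vessel inclination `phi` (upright geometry) scaled by
`sin(tilt)`; at zero flow this reduces exactly to the hydrostatic law
`dP = rho g dz sin(tilt)`.

The wall is an elastic beta-law with an optional Kelvin-Voigt term:

```
P = P_ext + (beta/A0) (sqrt(A) - sqrt(A0)) + Gamma/(A0 sqrt(A)) dA/dt
```

The elastic branch gives the closed-form wave speed

```
c = sqrt(beta / (2 rho A0)) A^(1/4)  =  sqrt((b + P) / (2 rho)),   b = beta/sqrt(A0),
```

used throughout as an independent oracle: vessels are parameterized by
their radius and target wave speed at a reference pressure of 100 mmHg
and `(A0, beta)` are recovered analytically.  Pressure-dependent
stiffening (`c` rising with `A^(1/4)`) is what lets posture-induced
wave-speed changes *emerge* from hydrostatic loading: no wall property
is rescaled when the body is tilted.

## Numerical scheme

The interior of each vessel is advanced with the two-step
(Richtmyer) Lax-Wendroff scheme on `(A, Q)`; the momentum flux carries
the conservative part of the pressure-gradient term
(`beta A^(3/2) / (3 rho A0)`), and the reference-area taper appears as
an analytically derived source so the continuum balance is exact.
Vessel ends are closed by Riemann characteristics `W± = U ± 4c`:

* **Inlet**: prescribed periodic flow plus the incoming backward
  characteristic (a prescribed-flow inlet is intentionally reflective,
  like a closed aortic valve in diastole).
* **Junctions**: Newton solve enforcing mass conservation and
  continuity of total pressure `P + rho U^2/2` across 1- or 2-daughter
  junctions, to a relative residual of 1e-13.
* **Terminals**: RCR Windkessel `dP_c/dt = (Q - (P_c - P_out)/R2)/C`
  with interface pressure `P = P_c + Q R1`; `C = 0` degenerates to a
  resistive load.  The outflow pressure gains the local hydrostatic
  column, mirroring the hydrostatic term carried by the downstream
  microvascular compartments, so perfusion is driven by heart-level
  pressure differences at any tilt.

A subtlety worth recording: characteristic extrapolation at boundaries
must include the characteristic source term (gravity, friction, and the
explicit `A0(x)` dependence of the tube law).  Without it, steep or
tapered vessels drift off hydrostatic equilibrium by tens of percent;
with it the discrete rest state matches `rho g dz` to fractions of a
percent (this is tested).

Time steps satisfy an advective CFL condition (Courant number 0.9)
plus, for visco-elastic walls, the explicit diffusion limit of the
Voigt source.  Beats are repeated (up to 30 by default) until the
beat-to-beat relative L2 change of pressure at monitored nodes falls
below 1e-3; the converged beat is sampled at 1 kHz at every cell
midpoint.  All analysis routines are sample-rate agnostic.

## The posture transform

Head-up tilt is modelled statically: the converged set-points of the
short-term regulation replace its dynamics.  The standing preset
applies heart rate +23% (time-rescaled inflow), stroke volume -32%
(amplitude-rescaled), cerebral terminal resistance -12% and compliance
+65%, non-cerebral terminal compliance -25%, and a single factor on
non-cerebral terminal resistances solved by bisection (0.1% tolerance)
so the parallel total of all terminal resistances rises by exactly
+39%; the tilt angle switches on the hydrostatic field.  Central venous
pressure, chamber elastance and venous volumes have no counterpart in
an open-loop arterial model; their omission is announced when the
transform is applied.  Wall stiffness is deliberately *not* scaled:
the wave-speed response to tilt is an output, not an input.

## Analysis conventions

* **PQ-/PU-loop windows**: from the pressure foot (the last sample
  below the pre-upstroke diastolic minimum + 1% of pulse pressure) to
  30% of the foot-to-peak time, widened in 5% steps to at most 60%
  until R^2 >= 0.98, else flagged.  Foot detection walks backwards from
  the systolic peak to the adjacent local minimum (on a lightly
  smoothed signal), which keeps late-diastolic oscillations from
  hijacking the window.
* **Separation** uses the PQ-loop impedance and retains mean levels, so
  hydrostatic shifts of mean forward/backward pressure are visible;
  pulse-pressure indices are insensitive to that choice.
* **Augmentation index**: zero-phase 25 Hz low-pass, then the systolic
  inflection from zero-crossings of the second derivative after the
  initial acceleration phase; a pre-peak shoulder gives AP > 0, a
  genuine post-peak shoulder (substantial positive curvature, pressure
  still well above diastolic) gives AP < 0, and a single smooth pulse
  is flagged rather than scored zero.
* **Backward bifurcation coefficient** is the mean of per-daughter
  magnitudes (the effective impedance seen from a daughter is the
  parallel of the parent and the remaining daughters).
* **Wave intensity** uses centered periodic differences; `t_back` is
  the energy-weighted backward arrival integrated over the full beat,
  as defined; `t_FCW` is the first forward-compression WI peak, with
  minor onset ripples (< 50% of the strongest forward peak) ignored.
* **Mean downstream speed** includes the current site, which makes the
  last aortic site's value equal its own local speed.
  The exclusive convention is available as an argument.

## The bundled fixtures and what they do (not) show

* `uniform_tube` — anechoic termination (`R1 = Z_c`, no distal
  resistance or compliance, `P_out` setting the working point).  With
  friction disabled and a small (5 ml) pulse, it is the reflection-free
  oracle: PU-loop speed within 2% of the analytic `c`, backward
  energy < 1%.
* `murray_tree` — radii follow Murray's law and per-level stiffness is
  solved so forward impedance is matched exactly; the forward area
  ratio is `2^(1/3)` by construction and the backward coefficient is
  0.5 at every junction.
* `single_reflector` — a stiffness step at 0.40 m with a sharp
  "ramp" wavelet (fast smooth rise, slow decay) resolved at 2.5 mm; the
  echo-timing oracle for ToR/PoR.  Oracle accuracy is limited by the
  centroid-versus-peak offset of the wavelet and by secondary inlet
  echoes; the bundled configuration keeps the apparent reflector
  within 5% of the true position.
* `mini_aorta` — a 14-vessel reduced adult tree: the conventional
  aortic site numbering (1, 63, 2, 14, 18, 27, 28, 35, 37, 39, 41),
  one cerebral-tagged carotid, one arm and one leg branch; upright
  elevations from -0.2 m (carotid tip) to +1.2 m (tibial tip); aortic
  wave-speed targets rising from ~3.9 to ~5.1 m/s, carotid 6.8,
  tibial 7.4 m/s at 100 mmHg; Windkessel terminals sized for a mean
  aortic pressure of 93 mmHg above a 33.2 mmHg outflow pressure at a
  cardiac output of 87.5 ml/s, split head 13% / arm 12% / legs 75%;
  lumped peripheral compliance ~1.1 ml/mmHg.  Its walls are
  visco-elastic (`Gamma = 150 sqrt(A0)`, about 3.4 Pa s m at the
  aorta — low-to-mid range for large human arteries): on a compact
  tree, centimetre-scale junction echoes otherwise ring through early
  systole and dominate loop-slope estimates; wall damping is also what
  the physiological arteries these vessels represent actually have.

What passing tests on these fixtures show is that the *methods* behave
correctly and that the qualitative posture physics (wave speeds up
below the heart and down at the carotid, terminal reflection up at limb
beds and down at cerebral beds, central reflection magnitude down,
reflection horizon receding) emerges from hydrostatics plus the
set-point shifts.  What they do not show: quantitative agreement with a
full-scale closed-loop circulation.  In particular, the 14-vessel tree
concentrates all lower-body outflow in one leg trunk, so distal-aortic
backward energy is dominated by discrete leg-terminal re-reflections;
the reflection-time (ToR) stability seen in richer anatomies holds here
only at proximal sites, and the package's own acceptance test records
that honestly rather than masking it.  Loop-based estimators carry
visible bias at strongly tapered or junction-adjacent sites (the
carotid PU-loop speed reads high); comparisons between postures are
therefore directional.

## Problem sizes and tolerances used by the test-suite

Simulations in the tests use the fixtures at their bundled resolutions:
~100 cells for the tube oracles, 280 cells for the reflector line,
~110 cells across the 14 mini-aorta vessels, sampled at 1-2 kHz, with
at most 30 beats to periodicity.  The supine/standing pair runs once
per session and is reused by all posture tests.  Key numerical
tolerances: junction residuals 1e-13 (relative), separation and WI
algebraic identities 1e-10, wave-speed oracle 0.1%, hydrostatic rest
state 1%, grid-refinement change of the beat peak < 1%.

## Known limitations

* Static posture surrogate: no transients, pre-syncope dynamics or
  long-duration adaptation; no baroreflex/cardiopulmonary/autoregulation
  ODEs.
* Open-loop: no venous return, heart chambers or valves; the inflow is
  prescribed, which makes the inlet fully reflective.
* The beta-law's pressure stiffening is gentler than exponential wall
  models, so tilt-induced wave-speed changes are smaller than in
  stiffer closed-loop models (same signs, smaller magnitudes).
* Exact Wilcoxon p-values require untied differences; ties fall back to
  the tie-corrected normal approximation.
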
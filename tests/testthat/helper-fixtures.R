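# Shared fixtures.  Expensive simulations are run once per session and
# cached; everything is generated in code.

.pw_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .pw_cache)) assign(key, builder(), envir = .pw_cache)
  get(key, envir = .pw_cache)
}

# frictionless matched uniform tube carrying a small pulse: the
# reflection-free oracle
matched_tube_sim <- function() {
  cache_get("matched_tube", function() {
    net <- canonical_network("uniform_tube")
    inf <- canonical_inflow("uniform_tube")
    simulate_beats(net, inf, posture = 0,
                   sim = sim_config(max_beats = 15, friction_coefficient = 0))
  })
}

# converged supine / standing beats on the bundled anatomical network
mini_sims <- function() {
  cache_get("mini_sims", function() {
    net <- canonical_network("mini_aorta")
    inf <- canonical_inflow("mini_aorta")
    sup <- simulate_beats(net, inf, posture_state("supine"), sim_config())
    std <- suppressMessages(
      simulate_beats(net, inf, posture_state("standing"), sim_config()))
    list(sup = sup, std = std,
         rep_sup = wave_analysis_report(sup),
         rep_std = wave_analysis_report(std))
  })
}

# sharp-wavelet echo fixture: impedance step at 0.40 m
reflector_sim <- function() {
  cache_get("reflector", function() {
    net <- canonical_network("single_reflector", reflector_at = 0.4,
                            z_step = 1.3, L = 0.3, mean_flow = 0.625e-6)
    inf <- canonical_inflow("single_reflector")
    simulate_beats(net, inf, posture = 0,
                   sim = sim_config(max_beats = 20, convergence_tol = 1e-6,
                                    friction_coefficient = 0,
                                    sample_rate = 2000))
  })
}

# single vessel + RCR Windkessel, for terminal/impedance tests
windkessel_sim <- function() {
  cache_get("windkessel", function() {
    v <- vessel_from_targets(1L, "demo", 0.1, 0.008, 0.008, 6, n_cells = 8L)
    Zc <- reference_impedance(v, 1050, mmHg_to_Pa(100), x = 0.1)
    tm <- terminal_windkessel(R1 = Zc, R2 = 2e8, C = 6e-9,
                              P_out = mmHg_to_Pa(10))
    net <- build_network(list(v), list(), list("1" = tm), 1L,
                         aortic_path = 1L)
    inf <- inflow_waveform(RR = 0.8, SV = 35e-6)
    simulate_beats(net, inf, posture = 0, sim = sim_config(max_beats = 25))
  })
}

# constant-flow inflow (for DC-limit checks)
constant_inflow <- function(q, RR = 0.8, n = 512L) {
  t <- seq(0, RR, length.out = n + 1L)
  structure(list(t = t, Q = rep(q, n + 1L), RR = RR, SV = q * RR,
                 shape = "constant", ejection_fraction = NA_real_),
            class = "pw_inflow")
}

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
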
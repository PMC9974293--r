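Package: pulsewave
Title: One-Dimensional Arterial Pulse-Wave Simulation and Wave Analysis
    Under Postural Change
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates converged heartbeats of pressure and flow on a
    one-dimensional arterial network (nonlinear tube law, gravity via
    hydrostatic loading, RCR Windkessel terminals, explicit
    Lax-Wendroff solver with characteristic junction coupling) and
    analyses the resulting pulse waves: forward/backward wave
    separation from PQ-/PU-loop characteristic impedance estimates,
    reflection magnitude and augmentation indices, reflection
    coefficients at bifurcations, tapers and terminal loads, input
    impedance spectra, wave-intensity analysis with wavefront
    classification, and the moving-horizon time/point-of-reflection
    (ToR/PoR) procedure along the aorta.  A head-up tilt transform
    maps a supine parameterization to standing (heart rate, stroke
    volume, peripheral resistance and compliance shifts plus the 90
    degree hydrostatic field), and paired Wilcoxon / ANCOVA helpers
    compare postures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
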
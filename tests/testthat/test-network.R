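# Network data model: topology validation, tube law, analytic wave
# speed, bifurcation area matching.

test_that("build_network accepts well-formed trees and rejects malformed ones", {
  v1 <- vessel_segment(1L, "root", 0.1, 1e-4, 1e-4, beta = 100, n_cells = 4L)
  tm <- terminal_windkessel(1e7, 1e8, 1e-9, 0)
  net <- build_network(list(v1), list(), list("1" = tm), root = 1L)
  expect_length(net$vessels, 1)
  expect_length(net$junctions, 0)
  expect_length(net$terminals, 1)

  # symmetric depth-1 tree: 3 vessels, 1 junction, 2 terminals
  tree <- canonical_network("murray_tree", depth = 1L)
  expect_length(tree$vessels, 3)
  expect_length(tree$junctions, 1)
  expect_length(tree$terminals, 2)

  mk <- function(n) vessel_segment(n, length = 0.1, A0_prox = 1e-4,
                                   beta = 100, n_cells = 4L)
  # vessel 2 daughter of both 1 and 3
  expect_error(
    build_network(list(mk(1), mk(2), mk(3)),
                  list(list(parent = 1, daughters = c(2, 3)),
                       list(parent = 3, daughters = 2)),
                  list("2" = tm), root = 1L),
    "daughter more than once")
  # cycle / unreachable
  expect_error(
    build_network(list(mk(1), mk(2), mk(3)),
                  list(list(parent = 2, daughters = 3),
                       list(parent = 3, daughters = 2)),
                  list("1" = tm), root = 1L),
    "topology error")
  # missing terminal on a leaf
  expect_error(
    build_network(list(mk(1), mk(2)),
                  list(list(parent = 1, daughters = 2)),
                  list(), root = 1L),
    "without a terminal")
  # duplicate ids
  expect_error(
    build_network(list(mk(1), mk(1)), list(), list("1" = tm), root = 1L),
    "duplicate vessel ids")
})

test_that("tube law reproduces the closed-form elastic and Voigt behaviour", {
  v <- vessel_segment(1L, "t", 0.1, A0_prox = 1e-4, beta = 2, Gamma = 0.5,
                      n_cells = 4L)
  # reference state
  expect_equal(tube_law(1e-4, 0, v, P_ext = 1234), 1234)
  # closed-form arithmetic: (2 / 1e-4) (sqrt(1.21e-4) - sqrt(1e-4)) = 20 Pa
  velast <- vessel_segment(1L, "t", 0.1, A0_prox = 1e-4, beta = 2,
                           n_cells = 4L)
  expect_equal(tube_law(1.21e-4, 0, velast), 20, tolerance = 1e-12)
  # Voigt damping raises pressure for expanding lumen
  expect_gt(tube_law(1.1e-4, 1e-6, v), tube_law(1.1e-4, 0, v))
  expect_error(tube_law(-1e-5, 0, v), "non-positive area")
  # inverse law round trip
  P <- mmHg_to_Pa(seq(20, 180, by = 20))
  expect_equal(tube_law(tube_law_area(P, velast), 0, velast), P,
               tolerance = 1e-12)
})

test_that("elastic branch is strictly monotone in area for bundled vessels", {
  net <- canonical_network("mini_aorta")
  for (v in net$vessels) {
    A <- seq(0.3, 3, length.out = 50) * v$A0_prox
    P <- tube_law(A, 0, v, x = 0)
    expect_true(all(diff(P) > 0))
  }
})

test_that("analytic wave speed matches closed form and scaling law", {
  v1 <- vessel_segment(1L, "a", 0.1, A0_prox = 1e-4, beta = 100, n_cells = 4L)
  v2 <- vessel_segment(2L, "b", 0.1, A0_prox = 1e-4, beta = 200, n_cells = 4L)
  A <- 1.3e-4
  expect_equal(wave_speed(A, v2) / wave_speed(A, v1), sqrt(2),
               tolerance = 1e-12)
  # A = A0 closed form
  expect_equal(wave_speed(1e-4, v1, rho = 1050),
               sqrt(100 / (2 * 1050 * 1e-4)) * (1e-4)^0.25,
               tolerance = 1e-12)
})

test_that("wave speed agrees with finite-difference (A/rho) dP/dA within 0.1%", {
  net <- canonical_network("mini_aorta")
  for (v in net$vessels) {
    x <- v$length / 2
    A0x <- v$A0_prox + (v$A0_dist - v$A0_prox) * x / v$length
    for (A in c(0.8, 1.0, 1.3) * A0x) {
      h <- 1e-7 * A
      dPdA <- (tube_law(A + h, 0, v, x) - tube_law(A - h, 0, v, x)) / (2 * h)
      c_fd <- sqrt(A / 1050 * dPdA)
      expect_rel(wave_speed(A, v, 1050, x), c_fd, 1e-3)
    }
  }
})

test_that("bifurcation area ratios follow Murray's law on the matched tree", {
  tree <- canonical_network("murray_tree", depth = 2L)
  ar <- network_area_ratios(tree)
  expect_equal(length(ar$ratio), 3L)
  expect_equal(ar$ratio, rep(2^(1 / 3), 3), tolerance = 1e-9)
  # close to the theoretical optimum ~1.25
  expect_lt(abs(ar$mean / 1.25 - 1), 0.015)
})

test_that("area ratio handles identities and continuations", {
  j <- list(parent = 1L, daughters = c(2L, 3L))
  # daughters jointly equal to parent
  expect_equal(area_ratio_bifurcation(j, rep(2e-4, 10),
                                      list(rep(1.2e-4, 10), rep(0.8e-4, 10))),
               1, tolerance = 1e-12)
  # zero pulsation equals static
  expect_equal(area_ratio_bifurcation(j, 2e-4, list(1e-4, 1e-4)),
               area_ratio_bifurcation(j, rep(2e-4, 5),
                                      list(rep(1e-4, 5), rep(1e-4, 5))))
  # continuation excluded with a notice
  expect_message(
    val <- area_ratio_bifurcation(list(parent = 1L, daughters = 2L),
                                  1e-4, list(1e-4)),
    "continuation")
  expect_true(is.na(val))
})
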
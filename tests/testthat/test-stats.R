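# Paired Wilcoxon signed-rank, ANCOVA line comparison, percent change.

# brute-force two-sided exact p by enumerating all 2^n sign assignments
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
}

test_that("monotone same-sign differences give the minimal two-sided p", {
  for (n in c(4, 6, 8, 10)) {
    w <- wilcoxon_signed_rank(rep(0, n), seq_len(n))
    expect_equal(w$p, 2 * 2^-n, tolerance = 1e-12)
    expect_equal(w$method, "exact")
  }
})

test_that("exact p agrees with full enumeration for n <= 8", {
  set.seed(42)
  for (k in 1:12) {
    n <- sample(3:8, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = 0.4)
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$p, wilcoxon_enum_p(y - x), tolerance = 1e-10)
    # cross-check against the reference implementation
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(w$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("ties and large n fall back to the normal approximation", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 3, 4, 5, 6, 8)        # tied |differences|
  w <- suppressMessages(wilcoxon_signed_rank(x, y))
  expect_equal(w$method, "normal-approx")
  ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                             correct = TRUE))
  expect_equal(w$p, unname(ref$p.value), tolerance = 1e-6)

  set.seed(5)
  xl <- rnorm(40); yl <- xl + rnorm(40, 0.3)
  wl <- wilcoxon_signed_rank(xl, yl)
  expect_equal(wl$method, "normal-approx")
})

test_that("zero differences are dropped and degenerate input errors", {
  expect_message(w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5),
                                           c(1, 3, 4, 5, 6)),
                 "dropped")
  expect_equal(w$n, 4L)
  expect_error(suppressMessages(wilcoxon_signed_rank(1:3, 1:3)),
               "all differences are zero")
})

test_that("percent change matches the printed iliac example and algebra", {
  expect_lt(abs(percent_change(5.06, 6.32) - 24.9), 0.05)
  expect_equal(percent_change(3.7, 3.7), 0)
  a <- 4.2; b <- 5.9
  expect_equal(percent_change(a, b), -percent_change(b, a) * b / a,
               tolerance = 1e-12)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("ANCOVA detects slope and intercept differences on synthetic lines", {
  set.seed(123)
  d <- seq(0, 0.5, length.out = 11)
  mk <- function(slope, icpt, g) data.frame(
    distance = d, time = icpt + slope * d + rnorm(11, 0, 0.002), group = g)

  diff_slope <- rbind(mk(0.19, 0.09, "supine"), mk(0.30, 0.09, "standing"))
  a1 <- ancova_compare_lines(diff_slope)
  expect_lt(a1$p_slope, 0.01)

  diff_icpt <- rbind(mk(0.22, 0.09, "fcw"), mk(0.22, 0.17, "bcw"))
  a2 <- ancova_compare_lines(diff_icpt)
  expect_gt(a2$p_slope, 0.05)
  expect_lt(a2$p_intercept, 0.01)

  degen <- rbind(mk(0.2, 0.1, "a")[1:2, ], mk(0.2, 0.1, "b"))
  expect_error(ancova_compare_lines(degen), "degenerate")
})

test_that("the slope test matches the classical two-line t-test", {
  set.seed(9)
  d <- seq(0, 0.5, length.out = 11)
  pts <- rbind(
    data.frame(distance = d, time = 0.1 + 0.2 * d + rnorm(11, 0, 0.004),
               group = "a"),
    data.frame(distance = d, time = 0.1 + 0.24 * d + rnorm(11, 0, 0.004),
               group = "b"))
  a <- ancova_compare_lines(pts)
  # textbook t-test for equality of two regression slopes (pooled SSE)
  f1 <- stats::lm(time ~ distance, pts[pts$group == "a", ])
  f2 <- stats::lm(time ~ distance, pts[pts$group == "b", ])
  sse <- sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2)
  s2 <- sse / (11 + 11 - 4)
  sxx <- sum((d - mean(d))^2)
  tstat <- (stats::coef(f1)[2] - stats::coef(f2)[2]) /
    sqrt(s2 * (1 / sxx + 1 / sxx))
  p_ref <- 2 * stats::pt(-abs(tstat), df = 18)
  expect_equal(a$p_slope, unname(p_ref), tolerance = 1e-9)
})
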
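# Paired statistics for posture comparisons: exact Wilcoxon signed-rank,
# ANCOVA on arrival-time regression lines, percentage changes.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples.  Zero differences are
#' dropped (with a notice).  For n <= 25 untied differences the p-value
#' is exact (signed-rank distribution); otherwise a normal approximation
#' with continuity (and tie) correction is used.
#'
#' @param x,y paired samples of equal length.
#' @return an object of class `pw_wilcoxon` with `n` (used pairs), `W`
#'   (sum of positive ranks), `p`, `method`, and the percentage change
#'   `delta_pct = 100 (mean(y) - mean(x)) / mean(x)`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  if (any(d == 0)) {
    message(sum(d == 0), " zero difference(s) dropped")
    d <- d[d != 0]
  }
  if (!length(d)) stop("all differences are zero: test undefined")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !tied) {
    # exact two-sided p from the null signed-rank distribution
    p_le <- stats::psignrank(W, n)
    p_ge <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_term <- if (tied) {
      tt <- table(abs(d)); sum(tt^3 - tt) / 48
    } else 0
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(n = n, W = W, p = p, method = method,
                 delta_pct = if (mean(x) == 0) NA_real_
                             else percent_change(mean(x), mean(y))),
            class = "pw_wilcoxon")
}

#' @export
print.pw_wilcoxon <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank (", x$method, "): n=", x$n,
      " W=", x$W, " p=", signif(x$p, 3),
      "  Delta%=", signif(x$delta_pct, 3), "\n", sep = "")
  invisible(x)
}

#' Percentage change from a baseline value
#'
#' `100 (standing - supine) / supine`.
#'
#' @param supine baseline value (non-zero).
#' @param standing comparison value.
#' @return percentage change.
#' @export
percent_change <- function(supine, standing) {
  if (any(supine == 0)) stop("zero baseline: percentage change undefined")
  100 * (standing - supine) / supine
}

#' ANCOVA comparison of two regression lines
#'
#' Fits `time ~ distance * group` and tests the interaction (equality of
#' slopes, F-test); the intercept difference is tested in the
#' common-slope model `time ~ distance + group`.  Used to compare
#' forward/backward arrival-time lines along the aorta between postures.
#'
#' @param points data frame with columns `distance`, `time`, `group`
#'   (two levels), at least 3 points and 2 distinct distances per group.
#' @return an object of class `pw_ancova` with per-group `slope` and
#'   `intercept`, `p_slope`, `p_intercept`.
#' @export
ancova_compare_lines <- function(points) {
  stopifnot(all(c("distance", "time", "group") %in% names(points)))
  points$group <- factor(points$group)
  if (nlevels(points$group) != 2) stop("exactly two groups required")
  for (g in levels(points$group)) {
    sub <- points[points$group == g, ]
    if (nrow(sub) < 3) stop("degenerate design: fewer than 3 points in group ", g)
    if (length(unique(sub$distance)) < 2)
      stop("degenerate design: collinear distances in group ", g)
  }
  full <- stats::lm(time ~ distance * group, data = points)
  common <- stats::lm(time ~ distance + group, data = points)
  an_int <- stats::anova(common, full)
  p_slope <- an_int[["Pr(>F)"]][2]
  an_grp <- stats::anova(stats::lm(time ~ distance, data = points), common)
  p_intercept <- an_grp[["Pr(>F)"]][2]
  fits <- lapply(split(points, points$group), function(sub)
    stats::coef(stats::lm(time ~ distance, data = sub)))
  structure(list(
    groups = levels(points$group),
    slope = vapply(fits, `[[`, numeric(1), "distance"),
    intercept = vapply(fits, `[[`, numeric(1), "(Intercept)"),
    p_slope = p_slope, p_intercept = p_intercept),
    class = "pw_ancova")
}

#' @export
print.pw_ancova <- function(x, ...) {
  cat("ANCOVA line comparison (", paste(x$groups, collapse = " vs "), ")\n",
      "  slopes:     ", paste(signif(x$slope, 4), collapse = " vs "),
      "  p = ", signif(x$p_slope, 3), "\n",
      "  intercepts: ", paste(signif(x$intercept, 4), collapse = " vs "),
      "  p = ", signif(x$p_intercept, 3), "\n", sep = "")
  invisible(x)
}
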
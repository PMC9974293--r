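# Head-up tilt as a static parameter transform: the converged set-points
# of the short-term regulation (heart rate, stroke volume, peripheral
# resistance and compliance, cerebral vasodilation) are applied as scale
# factors, and the tilt angle switches on the hydrostatic field in the
# solver.

#' Posture state and its haemodynamic scale factors
#'
#' The `"standing"` preset carries the steady-state shifts measured upon
#' passive head-up tilt from 0 to 90 degrees: heart rate +23%, stroke
#' volume -32%, total peripheral resistance +39%, cerebral arteriolar
#' resistance -12%, cerebral compliance +65%, non-cerebral peripheral
#' compliance -25%.  The `"supine"` preset is the identity at 0 degrees.
#'
#' @param name `"supine"`, `"standing"`, or `"custom"`.
#' @param theta tilt angle in degrees (0 supine ... 90 standing).
#' @param f_HR heart-rate factor (`RR <- RR / f_HR`).
#' @param f_SV stroke-volume factor.
#' @param f_TPR target factor on total peripheral resistance; the
#'   non-cerebral terminal resistances are scaled by a common factor
#'   solved so the parallel total meets this target exactly.
#' @param f_Rc cerebral terminal resistance factor.
#' @param f_Cc cerebral terminal compliance factor.
#' @param f_Cv non-cerebral terminal compliance factor.
#' @return an object of class `pw_posture`.
#' @export
posture_state <- function(name = c("supine", "standing", "custom"),
                          theta = NULL, f_HR = NULL, f_SV = NULL,
                          f_TPR = NULL, f_Rc = NULL, f_Cc = NULL,
                          f_Cv = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    supine  = list(theta = 0, f_HR = 1, f_SV = 1, f_TPR = 1,
                   f_Rc = 1, f_Cc = 1, f_Cv = 1),
    standing = list(theta = 90, f_HR = 1.23, f_SV = 0.68, f_TPR = 1.39,
                    f_Rc = 0.88, f_Cc = 1.65, f_Cv = 0.75),
    custom  = list(theta = 0, f_HR = 1, f_SV = 1, f_TPR = 1,
                   f_Rc = 1, f_Cc = 1, f_Cv = 1))
  p <- list(name = name,
            theta = theta %||% defaults$theta,
            f_HR = f_HR %||% defaults$f_HR,
            f_SV = f_SV %||% defaults$f_SV,
            f_TPR = f_TPR %||% defaults$f_TPR,
            f_Rc = f_Rc %||% defaults$f_Rc,
            f_Cc = f_Cc %||% defaults$f_Cc,
            f_Cv = f_Cv %||% defaults$f_Cv)
  with(p, stopifnot(theta >= 0, theta <= 90, f_HR > 0, f_SV > 0,
                    f_TPR > 0, f_Rc > 0, f_Cc > 0, f_Cv > 0))
  structure(p, class = "pw_posture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pw_posture <- function(x, ...) {
  cat("<pw_posture> ", x$name, " theta=", x$theta, " deg",
      "  f_HR=", x$f_HR, " f_SV=", x$f_SV, " f_TPR=", x$f_TPR,
      " f_Rc=", x$f_Rc, " f_Cc=", x$f_Cc, " f_Cv=", x$f_Cv, "\n", sep = "")
  invisible(x)
}

#' Apply a posture transform to a network and inflow
#'
#' Rescales the inflow (period and stroke volume), scales cerebral
#' terminal resistances and compliances by `f_Rc` / `f_Cc`, non-cerebral
#' terminal compliances by `f_Cv`, and solves (bisection, 0.1%
#' tolerance) for the single factor on non-cerebral terminal resistances
#' that makes the parallel total of all downstream resistances change by
#' exactly `f_TPR`.  Cerebral terminals are those attached to vessels
#' whose `group` is `"cerebral"`.  The closed-loop quantities that a
#' distributed-plus-lumped whole-circulation model would also shift
#' (central venous pressure, cardiac chamber elastance, venous volumes)
#' have no counterpart here; their omission is noted by message when a
#' non-identity preset is applied.
#'
#' @param network a `pw_network`.
#' @param inflow a `pw_inflow`.
#' @param posture a [posture_state()].
#' @return `list(network, inflow, f_R)` with modified copies and the
#'   solved non-cerebral resistance factor.
#' @export
apply_posture <- function(network, inflow, posture) {
  stopifnot(inherits(posture, "pw_posture"))
  identity_factors <- with(posture, all(c(f_HR, f_SV, f_TPR, f_Rc, f_Cc,
                                          f_Cv) == 1))
  if (identity_factors)
    return(list(network = network, inflow = inflow, f_R = 1))

  message("posture transform: applying static set-point factors; ",
          "closed-loop quantities (CVP, chamber elastance, venous ",
          "volumes) are not represented and remain unchanged")

  cerebral <- vapply(names(network$terminals), function(id)
    network_vessel(network, id)$group == "cerebral", logical(1))
  if (posture$f_Rc != 1 && !any(cerebral))
    stop("configuration error: no cerebral-tagged terminals but f_Rc != 1")

  R <- vapply(network$terminals, function(tm) tm$R_down, numeric(1))
  tpr0 <- 1 / sum(1 / R)
  target <- posture$f_TPR * tpr0
  Gc <- sum(1 / (R[cerebral] * posture$f_Rc))
  if (any(cerebral) && Gc >= 1 / target)
    stop("configuration error: requested TPR factor unreachable; ",
         "cerebral conductance alone exceeds the target")

  # bisection for the non-cerebral resistance factor
  tpr_with <- function(f) 1 / (Gc + sum(1 / (R[!cerebral] * f)))
  lo <- 1e-3; hi <- 1e3
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (tpr_with(mid) < target) lo <- mid else hi <- mid
    if (abs(tpr_with(mid) / target - 1) < 1e-3 && (hi / lo - 1) < 1e-3) break
  }
  f_R <- sqrt(lo * hi)

  terms <- network$terminals
  for (id in names(terms)) {
    tm <- terms[[id]]
    cere <- network_vessel(network, id)$group == "cerebral"
    fr <- if (cere) posture$f_Rc else f_R
    fc <- if (cere) posture$f_Cc else posture$f_Cv
    terms[[id]] <- terminal_windkessel(tm$R1 * fr, tm$R2 * fr,
                                       tm$C * fc, tm$P_out)
  }
  network$terminals <- terms
  inflow <- rescale_inflow(inflow, f_HR = posture$f_HR, f_SV = posture$f_SV)
  list(network = network, inflow = inflow, f_R = f_R)
}
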
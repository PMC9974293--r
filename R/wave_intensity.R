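# Wave intensity analysis and the moving-horizon (ToR/PoR) procedure.

#' Forward and backward wave intensity
#'
#' `WI_fb = +-(1 / 4 rho c) (dP/dt +- rho c dU/dt)^2` with centered
#' (periodic) finite differences for the time derivatives.  By
#' construction `WI_f >= 0 >= WI_b` everywhere and
#' `WI_f + WI_b = (dP/dt)(dU/dt)` pointwise.
#'
#' @param series a `pw_series` carrying velocity.
#' @param c local wave speed (m/s) — a number or a `pw_zc` from
#'   [estimate_c_pu()].
#' @param rho blood density (kg/m^3).
#' @return an object of class `pw_wi` with `t`, `WI_f`, `WI_b`, `dPdt`,
#'   `dUdt`, `rho_c` and `RR`.
#' @export
compute_wi <- function(series, c, rho = 1050) {
  if (inherits(c, "pw_zc")) c <- c$c
  stopifnot(is.numeric(c), c > 0)
  if (is.null(series$U)) stop("series carries no velocity")
  dt <- series$t[2] - series$t[1]
  dPdt <- central_diff_periodic(series$P, dt)
  dUdt <- central_diff_periodic(series$U, dt)
  rc <- rho * c
  WI_f <- (dPdt + rc * dUdt)^2 / (4 * rc)
  WI_b <- -(dPdt - rc * dUdt)^2 / (4 * rc)
  structure(list(t = series$t, WI_f = WI_f, WI_b = WI_b,
                 dPdt = dPdt, dUdt = dUdt, rho_c = rc, RR = series$RR,
                 vessel = series$vessel, cell = series$cell),
            class = "pw_wi")
}

central_diff_periodic <- function(y, dt) {
  n <- length(y)
  (y[c(2:n, 1)] - y[c(n, 1:(n - 1))]) / (2 * dt)
}

#' @export
plot.pw_wi <- function(x, ...) {
  graphics::plot(x$t / x$RR, x$WI_f, type = "l", col = "darkgreen",
                 xlab = "t / RR", ylab = "wave intensity",
                 ylim = range(c(x$WI_f, x$WI_b)), ...)
  graphics::lines(x$t / x$RR, x$WI_b, col = "firebrick")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# local maxima of y with prominence above prom (periodic signal treated
# linearly; endpoints are not peaks)
find_peaks <- function(y, prom) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- vapply(idx, function(i) {
    # prominence: height above the higher of the two bounding valleys
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    hl <- suppressWarnings(max(left[left > y[i]], -Inf))
    lv <- if (is.finite(hl)) {
      j <- max(which(left > y[i]))
      min(y[j:i])
    } else min(y[1:i])
    hr <- suppressWarnings(max(right[right > y[i]], -Inf))
    rv <- if (is.finite(hr)) {
      j <- i + min(which(right > y[i]))
      min(y[i:j])
    } else min(y[i:n])
    (y[i] - max(lv, rv)) >= prom
  }, logical(1))
  idx[keep]
}

#' Detect and classify wave-intensity peaks
#'
#' Local maxima of `WI_f` and of `|WI_b|` with prominence at least
#' `prominence` times the global maximum intensity are labelled as
#' forward/backward wavefronts; each is a compression wave if the
#' corresponding separated-pressure time derivative is positive at the
#' peak, a decompression wave otherwise (FCW/FDW/BCW/BDW).
#'
#' @param wi a `pw_wi`.
#' @param separation the matching `pw_separation` (provides `P_f`, `P_b`).
#' @param prominence prominence fraction in (0, 1).
#' @return data frame with columns `time`, `intensity`, `direction`,
#'   `type`, `label`; zero rows when nothing exceeds the threshold.
#' @export
classify_wavefronts <- function(wi, separation, prominence = 0.02) {
  stopifnot(prominence > 0, prominence < 1)
  dt <- wi$t[2] - wi$t[1]
  scale <- max(c(wi$WI_f, -wi$WI_b))
  if (scale <= 0)
    return(data.frame(time = numeric(0), intensity = numeric(0),
                      direction = character(0), type = character(0),
                      label = character(0)))
  prom <- prominence * scale
  dPf <- central_diff_periodic(separation$P_f, dt)
  dPb <- central_diff_periodic(separation$P_b, dt)
  fwd <- find_peaks(wi$WI_f, prom)
  bwd <- find_peaks(-wi$WI_b, prom)
  rows <- rbind(
    if (length(fwd)) data.frame(
      time = wi$t[fwd], intensity = wi$WI_f[fwd], direction = "forward",
      type = ifelse(dPf[fwd] > 0, "compression", "decompression")),
    if (length(bwd)) data.frame(
      time = wi$t[bwd], intensity = -wi$WI_b[bwd], direction = "backward",
      type = ifelse(dPb[bwd] > 0, "compression", "decompression")))
  if (is.null(rows) || !nrow(rows))
    return(data.frame(time = numeric(0), intensity = numeric(0),
                      direction = character(0), type = character(0),
                      label = character(0)))
  rows$label <- paste0(toupper(substr(rows$direction, 1, 1)),
                       toupper(substr(rows$type, 1, 1)), "W")
  rows[order(rows$time), , drop = FALSE]
}

#' Intensity-weighted mean arrival time of backward waves
#'
#' `t_back = int t WI_b dt / int WI_b dt` over the full beat (the
#' negative weights cancel, leaving a weighted mean within the beat).
#'
#' @param wi a `pw_wi`.
#' @return arrival time (s); errors when `WI_b` is identically zero
#'   (no visible reflection).
#' @export
backward_arrival_time <- function(wi) {
  denom <- trapz_uniform(wi$t, wi$WI_b)
  if (abs(denom) <= 1e-300 ||
      abs(denom) < 1e-14 * trapz_uniform(wi$t, abs(wi$WI_b) + wi$WI_f))
    stop("no backward wave energy: t_back undefined")
  trapz_uniform(wi$t, wi$t * wi$WI_b) / denom
}

#' Mean wave speed downstream of an aortic site
#'
#' Arithmetic mean of the per-site wave speeds from the given site to
#' the end of the aortic path.  The inclusive convention (current site
#' counted) makes the last site's value equal its own local wave speed.
#'
#' @param c_sites per-site wave speeds ordered root to iliac (m/s).
#' @param i site index.
#' @param inclusive include the current site (default) or only strictly
#'   downstream sites.
#' @return mean downstream speed (m/s).
#' @export
mean_downstream_speed <- function(c_sites, i, inclusive = TRUE) {
  stopifnot(i >= 1, i <= length(c_sites))
  from <- if (inclusive) i else min(i + 1, length(c_sites))
  mean(c_sites[from:length(c_sites)])
}

#' Time and point of reflection along the aortic path
#'
#' For every aortic site: the first forward-compression wavefront time
#' `t_FCW` (first FCW-classified peak of `WI_f`), the mean backward
#' arrival `t_back`, the time of reflection `ToR = t_back - t_FCW`, the
#' mean downstream wave speed, and the apparent point of reflection
#' `PoR = ToR * c_down / 2` — the distance below the site at which
#' backward waves appear to originate.  Sites with no backward wave
#' energy are excluded with a notice.
#'
#' @param sim a `pw_sim` over a network with an `aortic_path`.
#' @param rho blood density (kg/m^3).
#' @param prominence peak prominence fraction for wavefront detection.
#' @param inclusive convention for [mean_downstream_speed()].
#' @return an object of classes `pw_trapping`/`data.frame` with columns
#'   `site_id`, `distance_m`, `t_fcw_s`, `t_back_s`, `tor_s`,
#'   `c_down_m_s`, `por_m` and an attribute `arrivals` holding the
#'   (distance, time) point sets of the FCW and mean-backward arrivals.
#' @export
reflection_horizon <- function(sim, rho = sim$config$blood_density,
                               prominence = 0.02, inclusive = TRUE) {
  net <- sim$network
  if (is.null(net$aortic_path)) stop("network has no aortic path")
  path <- net$aortic_path

  # site = mid cell of each aortic-path vessel; distance measured along
  # the path from the root inlet to that cell midpoint
  dist <- numeric(length(path))
  run <- 0
  sites <- vector("list", length(path))
  for (k in seq_along(path)) {
    v <- network_vessel(net, path[k])
    cell <- max(1L, ceiling(v$n_cells / 2))
    x <- vessel_cell_x(v)[cell]
    dist[k] <- run + x
    run <- run + v$length
    sites[[k]] <- list(id = v$id, cell = cell)
  }

  rows <- list()
  fcw_pts <- list()
  for (k in seq_along(path)) {
    s <- sim_series(sim, sites[[k]]$id, sites[[k]]$cell)
    cpu <- estimate_c_pu(s, rho)
    zc <- estimate_zc_pq(s)
    sep <- separate_waves(s, zc)
    wi <- compute_wi(s, cpu, rho)
    peaks <- classify_wavefronts(wi, sep, prominence)
    fcw <- peaks[peaks$label == "FCW", , drop = FALSE]
    # first major forward compression: ignore onset ripples below half
    # the strongest forward intensity
    fcw <- fcw[fcw$intensity >= 0.5 * max(wi$WI_f), , drop = FALSE]
    t_fcw <- if (nrow(fcw)) fcw$time[1] else NA_real_
    t_back <- tryCatch(backward_arrival_time(wi), error = function(e) NA_real_)
    rows[[k]] <- data.frame(site_id = sites[[k]]$id, distance_m = dist[k],
                            t_fcw_s = t_fcw, t_back_s = t_back,
                            c_m_s = cpu$c)
  }
  tab <- do.call(rbind, rows)

  drop <- is.na(tab$t_back) | is.na(tab$t_fcw_s)
  if (any(drop))
    message("excluding sites with no visible backward waves: ",
            paste(tab$site_id[drop], collapse = ", "))

  c_down <- vapply(seq_len(nrow(tab)), function(i)
    mean_downstream_speed(tab$c_m_s, i, inclusive), numeric(1))
  tor <- tab$t_back_s - tab$t_fcw_s
  out <- data.frame(site_id = tab$site_id, distance_m = tab$distance_m,
                    t_fcw_s = tab$t_fcw_s, t_back_s = tab$t_back_s,
                    tor_s = tor, c_m_s = tab$c_m_s, c_down_m_s = c_down,
                    por_m = tor * c_down / 2)
  out <- out[!drop, , drop = FALSE]
  attr(out, "arrivals") <- list(
    fcw = data.frame(distance = tab$distance_m, time = tab$t_fcw_s),
    back = data.frame(distance = tab$distance_m, time = tab$t_back_s))
  class(out) <- c("pw_trapping", "data.frame")
  out
}

#' @export
print.pw_trapping <- function(x, ...) {
  cat("Aortic wave-trapping table (ToR/PoR):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
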
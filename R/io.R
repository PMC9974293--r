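# File formats.  Network descriptions are JSON (canonical) or YAML with
# clinical units (mmHg / cm / ml); waveforms are CSV per node with a
# JSON sidecar.  All values are converted to SI on load.

vessel_file_fields <- c("id", "name", "length", "A0_prox", "A0_dist",
                        "beta", "Gamma", "phi", "z_prox", "group",
                        "n_cells")
terminal_file_fields <- c("R1", "R2", "C", "P_out")

#' Write a network description file
#'
#' JSON document with top-level keys `vessels`, `junctions`,
#' `terminals`, `root`, `aortic_path`; lengths/elevations in cm, areas
#' in cm^2, stiffness in mmHg cm, resistances in mmHg s/ml, compliances
#' in ml/mmHg, pressures in mmHg.
#'
#' @param network a `pw_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  doc <- list(
    name = network$name,
    vessels = lapply(unname(network$vessels), function(v) list(
      id = v$id, name = v$name,
      length = v$length * 100,
      A0_prox = m2_to_cm2(v$A0_prox), A0_dist = m2_to_cm2(v$A0_dist),
      beta = v$beta / (MMHG_PA / 100),
      Gamma = v$Gamma / (MMHG_PA / 100),
      phi = v$phi, z_prox = v$z_prox * 100,
      group = v$group, n_cells = v$n_cells)),
    junctions = lapply(network$junctions, function(j)
      list(parent = j$parent, daughters = as.integer(j$daughters))),
    terminals = lapply(network$terminals, function(tm) list(
      R1 = SI_to_mmHg_s_ml(tm$R1), R2 = SI_to_mmHg_s_ml(tm$R2),
      C = SI_to_ml_mmHg(tm$C), P_out = Pa_to_mmHg(tm$P_out))),
    root = network$root,
    aortic_path = network$aortic_path)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network description file
#'
#' Accepts the JSON schema written by [write_network()] (YAML with the
#' same structure is accepted when the file extension is `.yml`/`.yaml`).
#' Unknown keys warn; missing required keys and dangling vessel
#' references error, naming the offender.
#'
#' @param path file path.
#' @return a validated `pw_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  known <- c("name", "vessels", "junctions", "terminals", "root",
             "aortic_path", "postures", "config")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("unknown top-level key(s) ignored: ", paste(extra, collapse = ", "))
  for (key in c("vessels", "terminals", "root"))
    if (is.null(doc[[key]])) stop("missing required key: ", key)

  vessels <- lapply(doc$vessels, function(v) {
    missing <- setdiff(c("id", "length", "A0_prox", "beta"), names(v))
    if (length(missing))
      stop("vessel entry missing required key(s): ",
           paste(missing, collapse = ", "))
    unknown <- setdiff(names(v), vessel_file_fields)
    if (length(unknown))
      warning("vessel ", v$id, ": unknown key(s) ignored: ",
              paste(unknown, collapse = ", "))
    vessel_segment(
      id = v$id, name = v$name %||% paste0("vessel_", v$id),
      length = v$length / 100,
      A0_prox = cm2_to_m2(v$A0_prox),
      A0_dist = cm2_to_m2(v$A0_dist %||% v$A0_prox),
      beta = v$beta * (MMHG_PA / 100),
      Gamma = (v$Gamma %||% 0) * (MMHG_PA / 100),
      phi = v$phi %||% 0, z_prox = (v$z_prox %||% 0) / 100,
      group = v$group %||% "other", n_cells = v$n_cells %||% 4L)
  })
  ids <- vapply(vessels, function(v) v$id, integer(1))
  junctions <- lapply(doc$junctions %||% list(), function(j) {
    ds <- unlist(j$daughters)
    bad <- setdiff(c(j$parent, ds), ids)
    if (length(bad))
      stop("junction references undefined vessel(s): ",
           paste(bad, collapse = ", "))
    list(parent = as.integer(j$parent), daughters = as.integer(ds))
  })
  terminals <- lapply(doc$terminals, function(tm) {
    missing <- setdiff(c("R1", "R2"), names(tm))
    if (length(missing))
      stop("terminal entry missing required key(s): ",
           paste(missing, collapse = ", "))
    terminal_windkessel(
      R1 = mmHg_s_ml_to_SI(tm$R1), R2 = mmHg_s_ml_to_SI(tm$R2),
      C = ml_mmHg_to_SI(tm$C %||% 0),
      P_out = mmHg_to_Pa(tm$P_out %||% 0))
  })
  bad_term <- setdiff(as.integer(names(doc$terminals)), ids)
  if (length(bad_term))
    stop("terminal references undefined vessel(s): ",
         paste(bad_term, collapse = ", "))
  build_network(vessels, junctions, terminals,
                root = doc$root,
                aortic_path = unlist(doc$aortic_path),
                name = doc$name %||% "network")
}

# fixed-format numeric for byte-stable CSV output
fmt_num <- function(x) sprintf("%.10g", x)

#' Write converged-beat waveforms of a simulation
#'
#' One CSV per cell with header `t_s,P_mmHg,Q_ml_s,A_cm2,U_cm_s` and a
#' JSON sidecar with location metadata and the beat period, plus a copy
#' of the network description (`network.json`) so the directory is
#' self-contained for the analysis commands.
#'
#' @param sim a `pw_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_waveforms <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(sim$network, file.path(dir, "network.json"))
  for (id in names(sim$P)) {
    v <- network_vessel(sim$network, id)
    for (e in seq_len(v$n_cells)) {
      s <- sim_series(sim, v$id, e)
      base <- sprintf("vessel%03d_cell%02d", v$id, e)
      tab <- cbind(fmt_num(s$t), fmt_num(Pa_to_mmHg(s$P)),
                   fmt_num(s$Q * 1e6), fmt_num(m2_to_cm2(s$A)),
                   fmt_num(s$U * 100))
      con <- file(file.path(dir, paste0(base, ".csv")), "wb")
      writeLines(c("t_s,P_mmHg,Q_ml_s,A_cm2,U_cm_s",
                   apply(tab, 1, paste, collapse = ",")), con)
      close(con)
      jsonlite::write_json(
        list(vessel_id = v$id, cell = e, x_m = s$x, z_m = s$z,
             RR_s = s$RR, tilt_deg = sim$tilt),
        file.path(dir, paste0(base, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Read waveform tables back into beat series
#'
#' @param dir directory written by [write_waveforms()] (or containing
#'   externally supplied CSVs of the same dialect; files without an `A`
#'   column yield series restricted to PQ-based analyses).
#' @return named list of `pw_series`, plus the network (if
#'   `network.json` is present) as attribute `network`.
#' @export
read_waveforms <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("(vessels|terminals|bifurcations|trapping|compare|wavefronts)",
                        basename(files))]
  if (!length(files)) stop("no waveform CSVs in ", dir)
  out <- list()
  for (f in files) {
    tab <- utils::read.csv(f, check.names = FALSE)
    need <- c("t_s", "P_mmHg", "Q_ml_s")
    missing <- setdiff(need, names(tab))
    if (length(missing))
      stop("file ", basename(f), " missing column(s): ",
           paste(missing, collapse = ", "))
    for (col in intersect(c("t_s", "P_mmHg", "Q_ml_s", "A_cm2"), names(tab))) {
      vals <- suppressWarnings(as.numeric(tab[[col]]))
      if (anyNA(vals))
        stop("parse error in ", basename(f), " column ", col, " at row ",
             which(is.na(vals))[1])
      tab[[col]] <- vals
    }
    dt <- diff(tab$t_s)
    if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
      stop("non-uniform time grid in ", basename(f))
    side <- sub("\\.csv$", ".json", f)
    meta <- if (file.exists(side))
      jsonlite::read_json(side, simplifyVector = TRUE)
    else list()
    A <- if ("A_cm2" %in% names(tab)) cm2_to_m2(tab$A_cm2) else NULL
    s <- hemo_series(tab$t_s, mmHg_to_Pa(tab$P_mmHg),
                     ml_s_to_m3_s(tab$Q_ml_s), A,
                     RR = meta$RR_s %||% (max(tab$t_s) + dt[1]),
                     vessel = meta$vessel_id %||% NA_integer_,
                     cell = meta$cell %||% NA_integer_,
                     x = meta$x_m %||% NA_real_, z = meta$z_m %||% NA_real_)
    out[[sub("\\.csv$", "", basename(f))]] <- s
  }
  netfile <- file.path(dir, "network.json")
  if (file.exists(netfile)) attr(out, "network") <- read_network(netfile)
  out
}

# reassemble a pw_sim-like object from a waveform directory
sim_from_waveforms <- function(dir) {
  series <- read_waveforms(dir)
  net <- attr(series, "network")
  if (is.null(net)) stop("waveform directory lacks network.json; ",
                         "analysis restricted to per-file operations")
  t <- series[[1]]$t
  RR <- series[[1]]$RR
  P <- list(); Q <- list(); A <- list()
  for (id in names(net$vessels)) {
    v <- net$vessels[[id]]
    Pm <- matrix(NA_real_, v$n_cells, length(t))
    Qm <- Pm; Am <- Pm
    for (e in seq_len(v$n_cells)) {
      key <- sprintf("vessel%03d_cell%02d", v$id, e)
      s <- series[[key]]
      if (is.null(s)) stop("missing waveform for vessel ", v$id, " cell ", e)
      Pm[e, ] <- s$P; Qm[e, ] <- s$Q
      if (!is.null(s$A)) Am[e, ] <- s$A
    }
    P[[id]] <- Pm; Q[[id]] <- Qm; A[[id]] <- Am
  }
  tilt <- 0
  side <- list.files(dir, pattern = "^vessel.*\\.json$", full.names = TRUE)
  if (length(side)) {
    meta <- jsonlite::read_json(side[1], simplifyVector = TRUE)
    tilt <- meta$tilt_deg %||% 0
  }
  inflow <- structure(list(t = t, Q = Q[[as.character(net$root)]][1, ],
                           RR = RR,
                           SV = trapz_uniform(t, Q[[as.character(net$root)]][1, ]),
                           shape = "loaded", ejection_fraction = NA_real_),
                      class = "pw_inflow")
  structure(list(t = t, P = P, Q = Q, A = A, network = net,
                 inflow = inflow, tilt = tilt, config = sim_config(),
                 convergence = NULL),
            class = "pw_sim")
}

#' Write a run manifest
#'
#' Records input file hashes, the configuration snapshot, package
#' version and seed so a run can be reproduced exactly.
#'
#' @param dir output directory.
#' @param command pipeline command name.
#' @param args named list of arguments (paths, flags).
#' @param inputs character vector of input file paths to hash.
#' @param seed integer seed recorded for reproducibility.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, args, inputs = character(0),
                           seed = NA_integer_) {
  man <- list(
    command = command,
    args = args,
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    package_version = as.character(utils::packageVersion("pulsewave")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
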
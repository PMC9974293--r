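# Pipeline commands tying simulation, analysis and reporting together.
# `run_pipeline()` is the programmatic interface; `pipeline_main()`
# parses a character vector of command-line style flags (used by the
# bundled Rscript wrapper in `inst/exec/`).

write_report_csv <- function(df, path) {
  cols <- names(df)
  rows <- apply(df, 1, function(r) paste(vapply(r, function(x) {
    if (is.na(suppressWarnings(as.numeric(x)))) as.character(x)
    else fmt_num(as.numeric(x))
  }, ""), collapse = ","))
  con <- file(path, "wb")
  writeLines(c(paste(cols, collapse = ","), rows), con)
  close(con)
  invisible(path)
}

resolve_network <- function(spec) {
  if (file.exists(spec)) read_network(spec) else canonical_network(spec)
}

resolve_posture <- function(spec) {
  if (is.null(spec) || identical(spec, "supine")) return(posture_state("supine"))
  if (identical(spec, "standing")) return(posture_state("standing"))
  if (file.exists(spec)) {
    doc <- jsonlite::read_json(spec, simplifyVector = TRUE)
    return(do.call(posture_state,
                   c(list(name = "custom"), doc[names(doc) != "name"])))
  }
  stop("usage error: unknown posture '", spec, "'")
}

resolve_inflow <- function(spec, network_name = NULL) {
  if (is.null(spec))
    return(canonical_inflow(network_name %||% "mini_aorta"))
  tab <- utils::read.csv(spec)
  if (!all(c("t_s", "Q_ml_s") %in% names(tab)))
    stop("inflow CSV needs columns t_s, Q_ml_s")
  structure(list(t = tab$t_s, Q = ml_s_to_m3_s(tab$Q_ml_s),
                 RR = max(tab$t_s),
                 SV = trapz_uniform(tab$t_s, ml_s_to_m3_s(tab$Q_ml_s)),
                 shape = "loaded", ejection_fraction = NA_real_),
            class = "pw_inflow")
}

#' Run a pipeline command
#'
#' Commands:
#' * `simulate`: `network` (path or canonical name), optional `inflow`
#'   CSV, `posture` (`"supine"`, `"standing"` or a JSON of factors),
#'   `out` directory.  Writes per-cell waveform CSVs, the network
#'   description and a manifest.
#' * `analyze`: `waves` directory; writes `vessels.csv`,
#'   `terminals.csv`, `bifurcations.csv`.
#' * `wia`: `waves` directory; writes `wavefronts.csv` (classified
#'   wave-intensity peaks per cell on the aortic path).
#' * `trapping`: `waves` directory; writes `trapping.csv` and
#'   `trapping_arrivals.json` (the arrival-time point sets).
#' * `compare-posture`: `supine` and `standing` waveform directories;
#'   writes `compare_posture.csv`.
#' * `fixtures`: `name` of a canonical network and `out` directory;
#'   writes the network JSON and its default inflow CSV.
#'
#' @param command one of the commands above.
#' @param ... named arguments as documented per command; `verbose = FALSE`
#'   silences progress messages.
#' @return invisibly, the primary result object of the command.
#' @export
run_pipeline <- function(command, ...) {
  args <- list(...)
  verbose <- isTRUE(args$verbose %||% TRUE)
  say <- function(...) if (verbose) message(...)
  command <- match.arg(command, c("simulate", "analyze", "wia", "trapping",
                                  "compare-posture", "fixtures"))
  switch(command,
    simulate = {
      if (is.null(args$network) || is.null(args$out))
        stop("usage error: simulate needs network= and out=")
      net <- resolve_network(args$network)
      posture <- resolve_posture(args$posture)
      inflow <- resolve_inflow(args$inflow, net$name)
      sim <- simulate_beats(net, inflow, posture,
                            sim = args$sim %||% sim_config())
      say("simulated ", sim$convergence$beats_run, " beats (converged: ",
          sim$convergence$converged, ")")
      write_waveforms(sim, args$out)
      write_manifest(args$out, "simulate",
                     args[setdiff(names(args), c("sim"))],
                     inputs = unlist(args[c("network", "inflow")][
                       vapply(args[c("network", "inflow")], function(x)
                         is.character(x) && file.exists(x), logical(1))]),
                     seed = args$seed %||% NA_integer_)
      invisible(sim)
    },
    analyze = {
      if (is.null(args$waves)) stop("usage error: analyze needs waves=")
      sim <- sim_from_waveforms(args$waves)
      rep <- wave_analysis_report(sim)
      write_report_csv(rep, file.path(args$waves, "vessels.csv"))
      write_report_csv(terminal_reflection(sim),
                       file.path(args$waves, "terminals.csv"))
      bif <- bifurcation_reflection(sim)
      if (!is.null(bif))
        write_report_csv(bif, file.path(args$waves, "bifurcations.csv"))
      say("analysis written to ", args$waves)
      invisible(rep)
    },
    wia = {
      if (is.null(args$waves)) stop("usage error: wia needs waves=")
      sim <- sim_from_waveforms(args$waves)
      net <- sim$network
      path <- net$aortic_path %||% net$root
      rows <- list()
      for (id in path) {
        v <- network_vessel(net, id)
        cell <- max(1L, ceiling(v$n_cells / 2))
        s <- sim_series(sim, id, cell)
        cpu <- estimate_c_pu(s)
        sep <- separate_waves(s, estimate_zc_pq(s))
        wi <- compute_wi(s, cpu)
        pk <- classify_wavefronts(wi, sep,
                                  args$prominence %||% 0.02)
        if (nrow(pk)) {
          pk$vessel_id <- id; pk$cell <- cell
          rows[[length(rows) + 1]] <- pk
        }
      }
      out <- do.call(rbind, rows)
      write_report_csv(out, file.path(args$waves, "wavefronts.csv"))
      say("wave-intensity peaks written to ", args$waves)
      invisible(out)
    },
    trapping = {
      if (is.null(args$waves)) stop("usage error: trapping needs waves=")
      sim <- sim_from_waveforms(args$waves)
      if (!is.null(args$aortic_path))
        sim$network$aortic_path <- as.integer(args$aortic_path)
      tr <- reflection_horizon(sim)
      write_report_csv(as.data.frame(tr), file.path(args$waves, "trapping.csv"))
      jsonlite::write_json(attr(tr, "arrivals"),
                           file.path(args$waves, "trapping_arrivals.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      say("trapping table written to ", args$waves)
      invisible(tr)
    },
    `compare-posture` = {
      if (is.null(args$supine) || is.null(args$standing))
        stop("usage error: compare-posture needs supine= and standing=")
      rs <- wave_analysis_report(sim_from_waveforms(args$supine))
      rt <- wave_analysis_report(sim_from_waveforms(args$standing))
      cmp <- compare_posture(rs, rt)
      out <- args$out %||% args$standing
      write_report_csv(cmp, file.path(out, "compare_posture.csv"))
      say("posture comparison written to ", out)
      invisible(cmp)
    },
    fixtures = {
      if (is.null(args$name) || is.null(args$out))
        stop("usage error: fixtures needs name= and out=")
      dir.create(args$out, recursive = TRUE, showWarnings = FALSE)
      net <- canonical_network(args$name)
      write_network(net, file.path(args$out, paste0(args$name, ".json")))
      inf <- canonical_inflow(args$name)
      con <- file(file.path(args$out, paste0(args$name, "_inflow.csv")), "wb")
      writeLines(c("t_s,Q_ml_s",
                   paste(fmt_num(inf$t), fmt_num(inf$Q * 1e6), sep = ",")),
                 con)
      close(con)
      say("fixture '", args$name, "' written to ", args$out)
      invisible(net)
    })
}

#' Command-line entry point
#'
#' Parses `argv` of the form `command --flag value ...` and dispatches
#' to [run_pipeline()].  Unknown flags raise a usage error.  Returns the
#' exit status (0 on success) so a wrapper script can `quit(status=)`.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return integer exit status, invisibly.
#' @export
pipeline_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pulsewave <command> [--flag value ...]",
    "commands: simulate analyze wia trapping compare-posture fixtures",
    "common flags: --network --inflow --posture --out --waves",
    "              --supine --standing --name --aortic-path --quiet",
    sep = "\n")
  status <- tryCatch({
    if (!length(argv)) stop("usage error: no command given")
    command <- argv[1]
    argv <- argv[-1]
    known <- c("network", "inflow", "posture", "out", "waves", "supine",
               "standing", "name", "aortic-path", "prominence",
               "verbose", "quiet")
    args <- list()
    i <- 1
    while (i <= length(argv)) {
      a <- argv[i]
      if (!startsWith(a, "--")) stop("usage error: expected a --flag, got ", a)
      key <- substring(a, 3)
      if (!key %in% known) stop("usage error: unknown flag --", key)
      if (key %in% c("verbose", "quiet")) {
        args$verbose <- key == "verbose"
        i <- i + 1
      } else {
        if (i == length(argv)) stop("usage error: --", key, " needs a value")
        val <- argv[i + 1]
        if (key == "aortic-path")
          args$aortic_path <- as.integer(strsplit(val, ",")[[1]])
        else if (key == "prominence")
          args$prominence <- as.numeric(val)
        else args[[key]] <- val
        i <- i + 2
      }
    }
    do.call(run_pipeline, c(list(command = command), args))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage)
    1L
  })
  invisible(status)
}
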
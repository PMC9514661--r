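## Serialization of the study inputs and outputs, run configuration, and
## the two pipeline drivers (single-scenario run and four-scenario
## treatment comparison).

activation_muscle_order <- function() c("tib_post", "fdl", "tib_ant", "edl",
                                        "ehl", "fhl", "per_long", "per_brev",
                                        "soleus")

#' Write / read activation profiles as CSV
#'
#' Activation profiles are stored as a 9-row by 10-column table with a
#' leading `muscle` label column; the row order is fixed (`tib_post, fdl,
#' tib_ant, edl, ehl, fhl, per_long, per_brev, soleus`) and the columns are
#' the control values at stance fractions `0, 1/9, ..., 1`.
#'
#' @param profiles named list of [activation_profile()]s.
#' @param path output / input file path.
#' @return `write_activation_csv` returns `path` invisibly;
#'   `read_activation_csv` returns the named list of profiles.
#' @export
write_activation_csv <- function(profiles, path) {
  ord <- activation_muscle_order()
  miss <- setdiff(ord, names(profiles))
  if (length(miss) > 0L)
    stop("missing profiles: ", paste(miss, collapse = ", "), call. = FALSE)
  m <- t(vapply(ord, function(nm) profiles[[nm]]$control_points, numeric(10)))
  df <- data.frame(muscle = ord, m)
  names(df) <- c("muscle", paste0("s", 0:9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activation_csv
#' @export
read_activation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("muscle", paste0("s", 0:9))))
    stop("not an activation profile table: ", path, call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    activation_profile(df$muscle[i], as.numeric(df[i, -1])))
  names(out) <- df$muscle
  out
}

#' Write / read a ground-plane trajectory as CSV
#'
#' The sample table (`t, x, y, z, roll, pitch, yaw`; seconds, metres,
#' degrees) is written with a comment header documenting the units and
#' Euler convention.  Any calibration offset is folded into the `y` column
#' on write.
#'
#' @param traj a [ground_trajectory()].
#' @param path output / input file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ground plane trajectory: t [s]; x,y,z [m]; roll,pitch,yaw [deg]",
    "# frame: x anterior, y up, z lateral; yaw about y, then pitch about the",
    "# rotated z (positive = anterior edge down, heel-strike attitude), then",
    "# roll about the twice-rotated x"), con)
  s <- traj$samples
  s$y <- s$y + traj$y_offset
  utils::write.csv(format(s, digits = 12), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ground_trajectory(as.data.frame(lapply(df, as.numeric)))
}

#' Write a simulation trace as CSV
#'
#' One row per output sample: time, percent stance, the five joint angles
#' and velocities (rad, rad/s), the vertical contact force of each sphere
#' (N), and the total vertical ground reaction force in body weights.
#'
#' @param trace a [simulate_stance()] trace.
#' @param path output file path.
#' @export
write_trace_csv <- function(trace, path) {
  q <- trace$q; colnames(q) <- paste0("q_", c("ankle", "subtalar", "arch",
                                              "mtp_medial", "mtp_lateral"))
  qd <- trace$qdot; colnames(qd) <- sub("^q_", "qd_", colnames(q))
  fy <- t(trace$sphere_f[2, , ])
  colnames(fy) <- paste0("fy_", trace$sphere_names)
  df <- data.frame(time = trace$time, pct_stance = trace$pct, q, qd, fy,
                   vgrf_bw = rowSums(fy) / trace$body_weight)
  utils::write.csv(format(df, digits = 10), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a simulation trace as an OpenSim-storage-style table
#'
#' Plain-text `.sto` table (name, row/column counts, version, `endheader`,
#' then a tab-separated table whose first column is time) interoperable
#' with common musculoskeletal tooling.
#'
#' @param trace a [simulate_stance()] trace.
#' @param path output file path (conventionally `.sto`).
#' @export
write_trace_sto <- function(trace, path) {
  fy <- t(trace$sphere_f[2, , ])
  tab <- cbind(time = trace$time, pct_stance = trace$pct, trace$q,
               trace$qdot, fy,
               vgrf_bw = rowSums(fy) / trace$body_weight)
  cn <- c("time", "pct_stance",
          paste0("q_", c("ankle", "subtalar", "arch", "mtp_medial",
                         "mtp_lateral")),
          paste0("qd_", c("ankle", "subtalar", "arch", "mtp_medial",
                          "mtp_lateral")),
          paste0("fy_", trace$sphere_names), "vgrf_bw")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("stance_trace_", tolower(trace$scenario)),
               "version=1",
               paste0("nRows=", nrow(tab)),
               paste0("nColumns=", ncol(tab)),
               "inDegrees=no",
               "endheader",
               paste(cn, collapse = "\t")), con)
  utils::write.table(format(tab, digits = 10), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles and validates the configuration of a simulation run: which
#' scenarios to simulate, calibration settings, the output directory and
#' integrator options.  A configuration can be written to and read from
#' YAML.
#'
#' @param scenarios character vector of scenario kinds.
#' @param out_dir output directory (created if needed by the run).
#' @param calibrate logical: run the body-weight calibration (on the
#'   arched model, shared across scenarios).
#' @param target_mass_kg calibration target mass (kg).
#' @param tol_bw calibration tolerance (body weights).
#' @param seed integer seed recorded in the configuration and used by the
#'   synthetic-input generators.
#' @param sim integrator options (`rtol`, `atol`, `n_out`).
#' @param params parameter bundle override (defaults used when `NULL`).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenarios = "ARCHED", out_dir = tempfile("archgait_"),
                       calibrate = TRUE, target_mass_kg = 82, tol_bw = 0.02,
                       seed = 1L, sim = NULL, params = NULL) {
  cfg <- list(scenarios = scenarios, out_dir = out_dir,
              calibrate = calibrate, target_mass_kg = target_mass_kg,
              tol_bw = tol_bw, seed = as.integer(seed), sim = sim,
              params = params)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$scenarios) || length(cfg$scenarios) < 1L)
    stop("config$scenarios: at least one scenario is required", call. = FALSE)
  bad <- setdiff(cfg$scenarios, scenario_kinds())
  if (length(bad) > 0L)
    stop("config$scenarios: unknown scenario(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1L)
    stop("config$out_dir: a single output directory path is required",
         call. = FALSE)
  if (!is.null(cfg$target_mass_kg) && cfg$target_mass_kg <= 0)
    stop("config$target_mass_kg: must be > 0", call. = FALSE)
  if (!is.null(cfg$tol_bw) && cfg$tol_bw <= 0)
    stop("config$tol_bw: must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg[c("scenarios", "out_dir", "calibrate",
                                 "target_mass_kg", "tol_bw", "seed")]), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

## short content hash of the parameter bundle, for the run log
params_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(params, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

## shared setup used by run_scenario / run_compare
prepare_run <- function(config) {
  validate_config(config)
  params <- if (is.null(config$params)) default_parameter_set() else config$params
  if (!is.null(config$seed)) params$sim$seed <- as.integer(config$seed)
  bundle <- default_input_bundle(params)
  cal <- NULL
  traj <- bundle$trajectory
  if (isTRUE(config$calibrate)) {
    arched <- build_foot_model("ARCHED", params)
    cal <- calibrate_heel_offset(arched, traj, bundle$profiles,
                                 target_mass_kg = config$target_mass_kg,
                                 tol = config$tol_bw)
    traj <- shift_trajectory(traj, cal$heel_offset)
  }
  list(params = params, bundle = bundle, traj = traj, cal = cal)
}

#' Run one or more stance simulations and write their outputs
#'
#' Builds the synthetic inputs, optionally calibrates the body-weight
#' loading on the arched model (the offset is shared by all scenarios),
#' simulates each configured scenario and writes, per scenario, the trace
#' as CSV and `.sto`, plus a YAML run log with the parameter hash, seed and
#' calibration result.  Outputs are deterministic: rerunning the same
#' configuration reproduces the files byte for byte.
#'
#' @param config a [run_config()].
#' @return named list of [simulate_stance()] traces (invisibly), with the
#'   calibration result and output paths as attributes.
#' @export
run_scenario <- function(config) {
  pr <- prepare_run(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- if (is.null(config$sim)) pr$params$sim else
    utils::modifyList(pr$params$sim, config$sim)
  traces <- list()
  paths <- character()
  for (kind in config$scenarios) {
    model <- build_foot_model(kind, pr$params)
    tr <- simulate_stance(model, pr$traj, pr$bundle$profiles, opts)
    base <- file.path(config$out_dir, tolower(kind))
    write_trace_csv(tr, paste0(base, "_trace.csv"))
    write_trace_sto(tr, paste0(base, "_trace.sto"))
    s <- grf_summary(tr)
    writeLines(utils::capture.output(print(s)), paste0(base, "_summary.txt"))
    paths <- c(paths, paste0(base, c("_trace.csv", "_trace.sto",
                                     "_summary.txt")))
    traces[[kind]] <- tr
  }
  log <- list(
    package_version = as.character(utils::packageVersion("archgait")),
    seed = config$seed,
    params_md5 = params_hash(pr$params),
    calibration = if (is.null(pr$cal)) NULL else
      list(heel_offset_m = pr$cal$heel_offset,
           achieved_peak_bw = pr$cal$achieved_peak,
           simulations = pr$cal$iterations),
    scenarios = config$scenarios
  )
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  attr(traces, "calibration") <- pr$cal
  attr(traces, "paths") <- paths
  invisible(traces)
}

#' Run the four-scenario treatment comparison
#'
#' Simulates all four foot configurations under one shared calibration and
#' writes the treatment-comparison report: a per-scenario summary CSV, a
#' human-readable markdown report (peak splits, lateral shifts,
#' restoration percentages, improvement ratio) and, optionally, plots of
#' the total and medial/lateral vertical ground reaction force curves.
#'
#' @param config a [run_config()] whose `scenarios` cover all four kinds.
#' @param plots logical: also write PNG figures.
#' @return the [compare_scenarios()] report (invisibly).
#' @export
run_compare <- function(config, plots = TRUE) {
  missing_sc <- setdiff(scenario_kinds(), config$scenarios)
  if (length(missing_sc) > 0L)
    stop("run_compare needs all four scenarios; missing: ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  traces <- run_scenario(config)
  rep <- compare_scenarios(traces)
  ## summary CSV
  sm <- do.call(rbind, lapply(rep$summaries, function(s)
    data.frame(scenario = s$scenario,
               peak1_bw = s$peak1["bw"], peak1_pct = s$peak1["pct"],
               valley_bw = s$valley["bw"], valley_pct = s$valley["pct"],
               peak2_bw = s$peak2["bw"], peak2_pct = s$peak2["pct"],
               medial_peak_bw = s$medial_peak,
               lateral_peak_bw = s$lateral_peak,
               medial_pct = s$medial_pct, lateral_pct = s$lateral_pct)))
  utils::write.csv(sm, file.path(config$out_dir, "comparison_summary.csv"),
                   row.names = FALSE)
  ## markdown report
  md <- c("# Treatment comparison", "",
          "Peak medial/lateral split of vertical ground reaction forces:", "",
          sprintf("- %s: %.1f%% / %.1f%%", names(rep$medial_pct),
                  rep$medial_pct, 100 - rep$medial_pct), "",
          sprintf("Lateral shift (vs untreated flatfoot): tendon transfer %.1f pp, implant-modified %.1f pp",
                  rep$shifts["FLATFOOT_TT"], rep$shifts["FLATFOOT_TT_IMPLANT"]),
          sprintf("Restoration of the arched distribution: tendon transfer %.1f%%, implant-modified %.1f%%",
                  rep$restorations["FLATFOOT_TT"],
                  rep$restorations["FLATFOOT_TT_IMPLANT"]),
          sprintf("Improvement ratio (implant / tendon transfer): %.2gX",
                  rep$improvement_ratio))
  writeLines(md, file.path(config$out_dir, "comparison_report.md"))
  if (isTRUE(plots)) {
    cols <- c(ARCHED = "black", FLATFOOT = "red", FLATFOOT_TT = "blue",
              FLATFOOT_TT_IMPLANT = "darkgreen")
    grDevices::png(file.path(config$out_dir, "vgrf_total.png"),
                   width = 900, height = 600)
    graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, 1.4),
                   xlab = "% stance", ylab = "vertical GRF (BW)",
                   main = "Total vertical ground reaction force")
    for (k in names(traces)) {
      v <- total_vgrf(traces[[k]])
      graphics::lines(v$pct, v$bw, col = cols[k], lwd = 2)
    }
    graphics::legend("topright", legend = names(traces),
                     col = cols[names(traces)], lwd = 2, bty = "n")
    grDevices::dev.off()
    grDevices::png(file.path(config$out_dir, "vgrf_medial_lateral.png"),
                   width = 900, height = 600)
    graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, 0.9),
                   xlab = "% stance", ylab = "vertical GRF (BW)",
                   main = "Medial (solid) and lateral (dashed) forefoot vGRF")
    for (k in names(traces)) {
      sp <- medial_lateral_peak_split(traces[[k]])
      graphics::lines(sp$medial$pct, sp$medial$bw, col = cols[k], lwd = 2)
      graphics::lines(sp$lateral$pct, sp$lateral$bw, col = cols[k], lwd = 2,
                      lty = 2)
    }
    graphics::legend("topleft", legend = names(traces),
                     col = cols[names(traces)], lwd = 2, bty = "n")
    grDevices::dev.off()
  }
  writeLines(utils::capture.output(print(rep)),
             file.path(config$out_dir, "comparison_report.txt"))
  invisible(rep)
}
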
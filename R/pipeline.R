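# End-to-end pipeline: one JSON config wires readers -> metrics/fits ->
# writers. Results land in an output directory as metric CSVs plus a single
# summary.json aggregating every stage's headline numbers; identical configs
# over identical inputs reproduce the summary bitwise.

read_trajectory_auto <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) read_multimodel_pdb(path)
  else read_frame_table(path)
}

sel_from_spec <- function(spec, default_label) {
  if (inherits(spec, "selection")) return(spec)
  selection(label = if (!is.null(spec$label)) spec$label else default_label,
            atom_name = spec$atom_name,
            residue_name = spec$residue_name,
            residue_number = spec$residue_number,
            chain_id = spec$chain_id)
}

stage_files <- function(stage) {
  unlist(stage[intersect(names(stage),
                         c("trajectory", "mobile", "reference", "input",
                           "model", "metric_csv", "correspondence"))])
}

run_stage <- function(stage, out_dir) {
  type <- stage$type
  headline <- list()
  if (type == "saltbridge") {
    traj <- read_trajectory_auto(stage$trajectory)
    spec <- salt_bridge_spec(
      sel_from_spec(stage$cation, "cation"),
      sel_from_spec(stage$anion, "anion"),
      threshold = if (!is.null(stage$threshold)) stage$threshold else 5,
      aggregator = if (!is.null(stage$aggregator)) stage$aggregator else "max")
    sb <- salt_bridge_series(traj, spec)
    occ <- occupancy(sb$formed,
                     frame_range = stage$frame_range)
    write_metric_csv(list(sb$distance, sb$formed),
                     file.path(out_dir, paste0(stage$name, ".csv")))
    headline <- list(occupancy = as.numeric(occ),
                     occupancy_percent = 100 * as.numeric(occ),
                     n_frames = length(sb$formed),
                     threshold = spec$threshold,
                     aggregator = spec$aggregator)
  } else if (type == "tilt") {
    traj <- read_trajectory_auto(stage$trajectory)
    surface <- fit_bilayer_surface(traj,
                                   sel_from_spec(stage$phosphates, "phosphates"))
    ts <- glycan_tilt_series(traj,
                             tilt_spec(sel_from_spec(stage$base, "base"),
                                       sel_from_spec(stage$tip, "tip")),
                             surface)
    write_metric_csv(ts, file.path(out_dir, paste0(stage$name, ".csv")))
    kr <- kde_mode(ts, bandwidth = stage$bandwidth)
    headline <- list(kde_mode = kr$mode, bandwidth = kr$bandwidth,
                     n_frames = length(ts))
  } else if (type == "domain_tilt") {
    traj <- read_trajectory_auto(stage$trajectory)
    surface <- fit_bilayer_surface(traj,
                                   sel_from_spec(stage$phosphates, "phosphates"))
    spec <- domain_axis_spec(
      sel_from_spec(stage$ca, "ca"),
      aux_distance = if (!is.null(stage$aux_distance)) stage$aux_distance else 10,
      mode = if (!is.null(stage$mode)) stage$mode else "pooled")
    ts <- domain_tilt_series(traj, spec, surface)
    write_metric_csv(ts, file.path(out_dir, paste0(stage$name, ".csv")))
    headline <- list(mean_tilt = mean(ts$values[ts$mask]),
                     n_frames = length(ts))
  } else if (type == "insertion") {
    traj <- read_trajectory_auto(stage$trajectory)
    surface <- fit_bilayer_surface(traj,
                                   sel_from_spec(stage$phosphates, "phosphates"))
    sel <- if (!is.null(stage$residue_name))
      sidechain_selection(stage$residue_name, stage$residue_number,
                          stage$chain_id)
    else sel_from_spec(stage$sidechain, "sidechain")
    ins <- insertion_series(traj, sel, surface,
                            leaflet = if (!is.null(stage$leaflet))
                              stage$leaflet else "upper")
    occ <- occupancy(ins$inserted)
    write_metric_csv(list(ins$depth, ins$inserted),
                     file.path(out_dir, paste0(stage$name, ".csv")))
    headline <- list(insertion_percent = 100 * as.numeric(occ),
                     n_frames = length(ins$inserted))
  } else if (type == "kde") {
    df <- utils::read.csv(stage$metric_csv)
    if (!stage$column %in% names(df))
      stop("column '", stage$column, "' not in ", stage$metric_csv)
    kr <- kde_mode(df[[stage$column]], bandwidth = stage$bandwidth)
    headline <- list(kde_mode = kr$mode, bandwidth = kr$bandwidth,
                     n = kr$n, degenerate = kr$degenerate)
  } else if (type == "rmsd") {
    mob <- read_trajectory_auto(stage$mobile)
    ref <- read_trajectory_auto(stage$reference)
    pair <- build_atom_map(
      mob, ref,
      pairing = if (!is.null(stage$pairing)) stage$pairing
                else "by_residue_number",
      correspondence = stage$correspondence,
      ca_only = isTRUE(stage$ca_only))
    sup <- kabsch_superpose(pair)
    headline <- list(rmsd = sup$rmsd, n_atoms = sup$n_atoms)
  } else if (type == "plddt") {
    model <- read_trajectory_auto(stage$model)
    cs <- plddt_summary(model)
    headline <- list(n_residues = cs$n_residues,
                     fraction_very_high = cs$fraction_very_high,
                     fraction_high = cs$fraction_high)
  } else if (type == "coin") {
    ds <- read_coin_csv(stage$input, p0 = stage$p0)
    fit <- coin_fit(ds)
    est <- coef(fit)
    curve <- data.frame(time_min = ds$times,
                        F_obs = fit$observed, F_fit = fitted(fit))
    utils::write.csv(curve, file.path(out_dir, paste0(stage$name, ".csv")),
                     row.names = FALSE)
    headline <- list(kd_uM = est[["kd"]], kd_mM = est[["kd"]] / 1000,
                     de = est[["de"]], cl_uM_per_min = est[["cl"]],
                     sse = fit$sse, converged = fit$converged,
                     n_points = fit$n)
  } else {
    stop("unknown stage type '", type, "'")
  }
  headline
}

#' Run an analysis pipeline from a single JSON config
#'
#' The config declares an output directory and an ordered list of stages
#' (`saltbridge`, `tilt`, `domain_tilt`, `insertion`, `kde`, `rmsd`,
#' `plddt`, `coin`), each naming its input files and parameters; selections
#' use the same JSON dialect as [read_selection_json()]. All referenced
#' files are validated before any stage runs. Each stage writes its metric
#' CSV and contributes headline numbers to `summary.json`; on stage failure
#' the partial summary is preserved with a failure report and an error is
#' raised (so a wrapping script exits non-zero).
#'
#' @param config path to a JSON config, or an equivalent list.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  if (is.null(config$output_dir)) stop("config needs output_dir")
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config declares no stages")
  stages <- config$stages
  nm <- vapply(stages, function(s) {
    if (is.null(s$name) || is.null(s$type))
      stop("every stage needs a name and a type")
    s$name
  }, "")
  if (anyDuplicated(nm)) stop("stage names must be unique")

  # validate every referenced file before running anything
  for (s in stages) {
    for (f in stage_files(s)) {
      if (is.character(f) && !file.exists(f))
        stop("config validation: file not found: ", f,
             " (stage '", s$name, "')")
    }
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary <- list(stages = stats::setNames(vector("list", length(stages)),
                                           nm))
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    message("pipeline: running stage '", s$name, "' (", s$type, ")")
    res <- tryCatch(run_stage(s, out_dir), error = function(e) e)
    if (inherits(res, "error")) {
      summary$failure <- list(stage = s$name, type = s$type,
                              message = conditionMessage(res))
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", s$name, "' failed: ", conditionMessage(res))
    }
    summary$stages[[s$name]] <- res
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
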
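pipeline_allowed_keys <- c(
  "stages", "outdir", "seed", "psi", "temperature", "M_ref", "fold_threshold",
  "titration_table", "salt_table", "lane_table", "mutant_table",
  "delta_aicc", "kd2_range_factor", "amplitude_factor"
)

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a path to a JSON file holding one).
#' Unknown keys are rejected before any computation; thresholds must be
#' positive. Recognized keys: `stages` (subset of `simulate`, `fit`, `salt`,
#' `stoich`, `mutscan`), `outdir`, `seed`, `psi`, `temperature`, `M_ref`,
#' `fold_threshold`, `delta_aicc`, `kd2_range_factor`, `amplitude_factor`,
#' and per-stage input paths `titration_table`, `salt_table`, `lane_table`,
#' `mutant_table` (when absent, the simulate stage must provide them).
#'
#' @param config named list or JSON file path.
#' @return The validated, default-filled configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config) || (length(config) && is.null(names(config))))
    stop_equibind("config must be a named list or a JSON object",
                  "equibind_config_error")
  unknown <- setdiff(names(config), pipeline_allowed_keys)
  if (length(unknown))
    stop_equibind(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "equibind_config_error")
  defaults <- list(stages = c("simulate", "fit", "salt", "stoich", "mutscan"),
                   outdir = "equibind_run", seed = 0L, psi = 0.695,
                   temperature = 298.15, M_ref = 0.15, fold_threshold = 2.5,
                   delta_aicc = 2, kd2_range_factor = 10, amplitude_factor = 3)
  cfg <- utils::modifyList(defaults, config)
  bad_stage <- setdiff(cfg$stages, c("simulate", "fit", "salt", "stoich",
                                     "mutscan"))
  if (length(bad_stage))
    stop_equibind(sprintf("unknown stage(s): %s",
                          paste(bad_stage, collapse = ", ")),
                  "equibind_config_error")
  for (k in c("psi", "temperature", "M_ref", "fold_threshold", "delta_aicc",
              "kd2_range_factor", "amplitude_factor")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_equibind(sprintf("config key `%s` must be a single positive number", k),
                    "equibind_config_error")
  }
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the requested stages and writes one report per stage plus a run
#' manifest (configuration echo, seed, package and R versions, timestamp)
#' under `outdir`. The `simulate` stage writes synthetic input tables (and a
#' JSON truth sidecar) which later stages consume when no explicit input path
#' is configured. Numeric report contents are reproducible byte-for-byte
#' under a fixed seed.
#'
#' @param config a configuration accepted by [run_config()].
#' @return Invisibly, a list of per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  inputs <- list(titration = cfg$titration_table %||% NULL,
                 salt = cfg$salt_table %||% NULL,
                 lanes = cfg$lane_table %||% NULL,
                 mutants = cfg$mutant_table %||% NULL)

  if ("simulate" %in% cfg$stages) {
    truth <- list(
      titration = list(A0 = 0.05, A1 = 0.15, KD1 = 2.1e-9, Rt = 2e-9),
      salt = list(Z = 8.2, psi = cfg$psi, KA_1M = 1),
      emsa = list(Nt = 2e-6, KD1 = 2e-9, KD2 = 2e-8),
      seed = cfg$seed
    )
    curves <- simulate_titration(
      simulation_design(),
      binding_parameters(A0 = 0.05, A1 = 0.15, KD1 = 2.1e-9, Rt = 2e-9),
      sample_id = "sim", seed = cfg$seed)
    f_tit <- file.path(cfg$outdir, "titration.csv")
    write_titration_table(curves, f_tit)

    ss <- simulate_salt_series(Z = 8.2, psi = cfg$psi, KA_1M = 1,
                               sdlog = 0.05, seed = cfg$seed + 1L)
    f_salt <- file.path(cfg$outdir, "salt.csv")
    write_table(data.frame(sample_id = ss$sample_id, salt_M = ss$M,
                           KD_M = ss$KD), f_salt)

    lanes <- simulate_emsa(Nt = 2e-6, KD1 = 2e-9, KD2 = 2e-8,
                           fraction_sd = 0.01, loading_sdlog = 0.05,
                           seed = cfg$seed + 2L)
    f_lanes <- file.path(cfg$outdir, "lanes.csv")
    write_table(cbind(sample_id = "sim_emsa", lanes), f_lanes)

    panel <- simulate_mutant_panel(seed = cfg$seed + 3L)
    f_mut <- file.path(cfg$outdir, "mutants.csv")
    write_table(panel, f_mut)

    jsonlite::write_json(truth, file.path(cfg$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    inputs$titration <- inputs$titration %||% f_tit
    inputs$salt <- inputs$salt %||% f_salt
    inputs$lanes <- inputs$lanes %||% f_lanes
    inputs$mutants <- inputs$mutants %||% f_mut
    results$simulate <- list(titration = f_tit, salt = f_salt,
                             lanes = f_lanes, mutants = f_mut)
  }

  if ("fit" %in% cfg$stages) {
    if (is.null(inputs$titration))
      stop_equibind("fit stage needs `titration_table` or the simulate stage",
                    "equibind_config_error")
    curves <- read_titration_table(inputs$titration)
    rep <- fit_report(curves)
    write_table(rep, file.path(cfg$outdir, "fit_report.csv"))
    results$fit <- rep
  }

  if ("salt" %in% cfg$stages) {
    if (is.null(inputs$salt))
      stop_equibind("salt stage needs `salt_table` or the simulate stage",
                    "equibind_config_error")
    series <- read_salt_table(inputs$salt, cfg$temperature)
    rows <- lapply(series, function(s) {
      sf <- analyze_salt_series(s, psi = cfg$psi, M_ref = cfg$M_ref)
      data.frame(sample_id = sf$sample_id, slope = sf$slope,
                 slope_se = sf$slope_se, Z = sf$Z, dG_obs = sf$dG_obs,
                 dG_el = sf$dG_el, dG_nel = sf$dG_nel, M_ref = sf$M_ref,
                 psi = sf$psi, temperature_K = sf$temperature)
    })
    rep <- do.call(rbind, rows); rownames(rep) <- NULL
    write_table(rep, file.path(cfg$outdir, "salt_report.csv"))
    results$salt <- rep
  }

  if ("stoich" %in% cfg$stages) {
    if (is.null(inputs$lanes))
      stop_equibind("stoich stage needs `lane_table` or the simulate stage",
                    "equibind_config_error")
    lanes <- read_lane_table(inputs$lanes)
    rows <- lapply(names(lanes), function(id) {
      g <- lanes[[id]]
      fr <- lane_fractions(g$F, g$B1, g$B2)
      bp1 <- find_breakpoint(g$ratio, fr$f_B1)
      bp2 <- find_breakpoint(g$ratio, protein_occupancy(fr))
      data.frame(sample_id = id, breakpoint_B1 = bp1$breakpoint,
                 breakpoint_occupancy = bp2$breakpoint,
                 shape_B1 = bp1$shape, shape_occupancy = bp2$shape)
    })
    rep <- do.call(rbind, rows); rownames(rep) <- NULL
    write_table(rep, file.path(cfg$outdir, "stoich_report.csv"))
    results$stoich <- rep
  }

  if ("mutscan" %in% cfg$stages) {
    if (is.null(inputs$mutants))
      stop_equibind("mutscan stage needs `mutant_table` or the simulate stage",
                    "equibind_config_error")
    panel <- read_mutant_table(inputs$mutants)
    res <- analyze_mutant_panel(panel, fold_threshold = cfg$fold_threshold)
    write_table(res$comparison, file.path(cfg$outdir, "mutscan_report.csv"))
    counts <- res$classification[c("n_mutants", "affected_either",
                                   "rna_greater", "basic_affected",
                                   "basic_rna_greater")]
    jsonlite::write_json(counts, file.path(cfg$outdir, "mutscan_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    results$mutscan <- res
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "outdir")],
    package_version = as.character(utils::packageVersion("equibind")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
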
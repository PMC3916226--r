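# End-to-end reproducible runs: one configuration object, one seed, and a
# manifest with content digests of every file written.

#' Build a run configuration
#'
#' @param scenarios Character vector of scenario names from
#'   [scenario_catalog()] (the nominal model is always run).
#' @param parameter_file Optional JSON file from [write_parameters()];
#'   `NULL` uses the shipped nominal manifest.
#' @param t_end Simulation window, minutes.
#' @param ensemble `NULL`, or a list with `n` and `fraction` to run a
#'   parameter-uncertainty ensemble for each scenario.
#' @param synth `NULL`, or a list with `cv` (ELISA noise) and `sd_ct` to
#'   generate synthetic assay datasets comparing nominal and the first
#'   scenario.
#' @param alpha Significance level for the statistics stage.
#' @param seed Integer seed funnelling all randomness.
#' @return List of class `nfkb_config`.
#' @export
run_config <- function(scenarios = c("Fig6A_combined"), parameter_file = NULL,
                       t_end = 150, ensemble = NULL,
                       synth = list(cv = 0.15, sd_ct = 0.25), alpha = 0.05,
                       seed = 1) {
  structure(list(scenarios = scenarios, parameter_file = parameter_file,
                 t_end = t_end, ensemble = ensemble, synth = synth,
                 alpha = alpha, seed = as.integer(seed)),
            class = "nfkb_config")
}

#' Run the full pipeline
#'
#' Executes equilibrate -> stimulate for the nominal model and every
#' configured scenario, classifies each scenario, optionally runs ensembles
#' and generates synthetic assay data with the per-time-point statistics, and
#' writes every output (trajectory CSVs, verdict JSONs, datasets) plus a
#' manifest of MD5 content digests to `out_dir`.
#'
#' @param config `nfkb_config` from [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: list of output files and their digests.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "nfkb_config"))
  if (is.null(config$scenarios) || !length(config$scenarios))
    stop("config must name at least one scenario")
  catalog <- scenario_catalog()
  unknown <- setdiff(config$scenarios, names(catalog))
  if (length(unknown))
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$parameter_file) && !file.exists(config$parameter_file))
    stop("parameter file not found: ", config$parameter_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$parameter_file)) {
    params <- default_parameters()
    pools <- default_pools()
  } else {
    pp <- read_parameters(config$parameter_file)
    params <- pp$params
    pools <- pp$pools
  }

  files <- character(0)
  nominal <- simulate_scenario(NULL, params, pools, t_end = config$t_end)
  f <- file.path(out_dir, "trajectory_nominal.csv")
  write_trajectory(nominal, f)
  files <- c(files, f, sub("\\.csv$", ".json", f))

  runs <- list(nominal = nominal)
  for (nm in setdiff(config$scenarios, "nominal")) {
    scn <- catalog[[nm]]
    traj <- simulate_scenario(scn, params, pools, t_end = config$t_end)
    runs[[nm]] <- traj
    f <- file.path(out_dir, sprintf("trajectory_%s.csv", nm))
    write_trajectory(traj, f)
    files <- c(files, f, sub("\\.csv$", ".json", f))
    verdict <- evaluate_scenario(scn, nominal, traj)
    f <- file.path(out_dir, sprintf("verdict_%s.json", nm))
    jsonlite::write_json(unclass(verdict), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  if (!is.null(config$ensemble)) {
    samples <- sample_parameters(params, pools,
                                 fraction = config$ensemble$fraction,
                                 n = config$ensemble$n, seed = config$seed)
    for (nm in config$scenarios) {
      scn <- if (nm == "nominal") NULL else catalog[[nm]]
      ens <- run_ensemble(samples, scn, t_end = config$t_end)
      f <- file.path(out_dir, sprintf("ensemble_mean_%s.csv", nm))
      write_trajectory(ens$mean, f)
      files <- c(files, f, sub("\\.csv$", ".json", f))
    }
  }

  if (!is.null(config$synth)) {
    scen_traj <- runs[[setdiff(config$scenarios, "nominal")[1L]]]
    if (is.null(scen_traj)) scen_traj <- nominal
    stats_out <- list()
    for (assay in names(assay_specs())) {
      ds <- generate_assay(nominal, scen_traj, assay = assay,
                           cv = config$synth$cv, seed = config$seed)
      both <- rbind(ds$control, ds$scenario)
      f <- file.path(out_dir, sprintf("assay_%s.csv", assay))
      utils::write.csv(both, f, row.names = FALSE)
      files <- c(files, f)
      stats_out[[assay]] <- lapply(
        compare_groups(both, alpha = config$alpha),
        function(g) list(time = g$time, F = g$F, p = g$p,
                         pairwise = as.data.frame(g$pairwise)))
    }
    ct <- generate_qpcr(nominal, seed = config$seed,
                        sd_ct = config$synth$sd_ct)
    fc <- ddct_fold_change(ct)
    f <- file.path(out_dir, "qpcr_fold_changes.csv")
    utils::write.csv(fc, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "stats_report.json")
    jsonlite::write_json(stats_out, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  manifest <- list(
    config = unclass(config),
    params_digest = .params_digest(params, pools),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
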
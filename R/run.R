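.provenance <- function(config) {
  list(config_hash = config_hash(config), seed = config$seed,
       package_version = as.character(utils::packageVersion("pedroute")))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the Monte Carlo sweep for the configured variants
#'
#' Executes [sweep_counts()] for every variant in `config$sweep$variants` and
#' writes, under `out_dir`, one long-format CSV
#' (`ensemble_<variant>.csv`: variant, N, k, probability) per variant plus a
#' JSON summary (`ensemble_summary.json`) with the mean occupancies, herding
#' probabilities, activation thresholds, and provenance (config hash, seed).
#'
#' @param config A `run_config` (validated).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of `ensemble_statistics` objects.
#' @export
run_simulate <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(config)
  fd <- config_fd(config)
  emg <- config_emg(config)
  lf <- config_lambda_fixed(config)
  n_range <- seq.int(config$sweep$n_min, config$sweep$n_max)
  out <- list()
  for (v in config$sweep$variants) {
    message(sprintf("[simulate] variant=%s N=%d..%d m=%d", v,
                    min(n_range), max(n_range), config$sweep$realizations))
    st <- sweep_counts(v, geom, fd, emg, n_range,
                       config$sweep$realizations, config$seed, lf)
    data.table::fwrite(st$p_nb, file.path(out_dir,
                                          paste0("ensemble_", v, ".csv")))
    out[[v]] <- st
  }
  summary <- list(
    provenance = .provenance(config),
    lambda_fixed = lf,
    variants = lapply(out, function(st) {
      act <- tryCatch(estimate_activation_threshold(st),
                      error = function(e) NA_integer_)
      list(n = st$n_values, mean_n_a = st$mean_n_a,
           mean_n_b = st$mean_n_b, p_empty_b = st$p_empty_b,
           activation_threshold = act)
    }))
  .write_json(summary, file.path(out_dir, "ensemble_summary.json"))
  invisible(out)
}

#' Generate the configured synthetic dataset
#'
#' Builds the [dataset_manifest()] from the configuration, generates the
#' frames (with positions filled along the path templates), and writes them in
#' the frame-record CSV dialect together with a sidecar provenance JSON
#' (`<out>.meta.json`). With `n_frames = 0` a header-only CSV is written.
#'
#' @param config A `run_config` (validated).
#' @param out_path Output CSV path.
#' @return Invisibly, the generated records.
#' @export
run_generate <- function(config, out_path) {
  config <- validate_config(config)
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  man <- dataset_manifest(
    n_frames = config$dataset$n_frames,
    fd = config_fd(config), emg = config_emg(config),
    geom = config_geometry(config), seed = config$seed,
    count_law = config$dataset$count_law,
    measurement_sd = config$dataset$measurement_sd)
  message(sprintf("[generate] %d frames -> %s", man$n_frames, out_path))
  rec <- generate_frames(man)
  rec <- generate_positions(rec, config_geometry(config))
  write_frames(rec, out_path)
  .write_json(c(.provenance(config),
                list(n_frames = man$n_frames, n_records = nrow(rec))),
              paste0(out_path, ".meta.json"))
  invisible(rec)
}

#' Run the full empirical pipeline on a dataset
#'
#' Reads a frame-record CSV and computes: occupancy curves and the empirical
#' activation threshold, the pooled and per-path fundamental-diagram fits, the
#' global diagrams with the local-slope reconstruction check, the
#' perceived-ratio series and its EMG fit, the flow table with analytic
#' bounds, and the herding probabilities. Writes one tidy CSV per
#' figure-equivalent plus a `metrics.json` summary, all stamped with the
#' config hash and seed. The comparison table holds the data-side herding
#' probabilities next to full-model Monte Carlo predictions at the configured
#' parameters (`model_realizations = 0` skips the model side).
#'
#' @param data_path Path to a frame-record CSV.
#' @param config A `run_config` (validated).
#' @param out_dir Output directory.
#' @param model_realizations Realizations per N for the model comparison.
#' @return Invisibly, a list with all computed objects.
#' @export
run_analyze <- function(data_path, config, out_dir,
                        model_realizations = 0L) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_frames(data_path)
  if (!nrow(records))
    stop("insufficient data: dataset is empty")
  message(sprintf("[analyze] %d records in %d frames", nrow(records),
                  length(unique(records$frame_id))))

  occ <- occupancy_statistics(records)
  fit <- fit_local_diagram(records)
  gd <- global_diagram(records, fit$kappa_hat)
  series <- lambda_p_series(records)
  lam_fit <- if (length(series) >= 100L) fit_lambda_p(series) else NULL
  if (is.null(lam_fit))
    message(sprintf(
      "[analyze] perceived-ratio series too short to fit (%d frames with both paths occupied; %d skipped)",
      length(series), attr(series, "n_skipped")))
  flow <- if (fit$kappa_hat > 0) flow_analysis(records, fit) else NULL
  herd <- herding_probability(records)

  data.table::fwrite(occ$table, file.path(out_dir, "fig3_occupancy.csv"))
  data.table::fwrite(gd, file.path(out_dir, "fig4_diagrams.csv"))
  if (!is.null(flow))
    data.table::fwrite(flow$table, file.path(out_dir, "fig5_flow.csv"))
  # binned PDF of the ratio series (the figure-equivalent summary), with the
  # fitted EMG density alongside when available
  if (length(series)) {
    h <- graphics::hist(as.numeric(series), breaks = 60, plot = FALSE)
    lam_tab <- data.table::data.table(
      lambda_p_mid = h$mids, pdf = h$density,
      emg_fit_pdf = if (!is.null(lam_fit)) demg(h$mids, lam_fit$params)
                    else NA_real_)
  } else {
    lam_tab <- data.table::data.table(lambda_p_mid = numeric(0),
                                      pdf = numeric(0),
                                      emg_fit_pdf = numeric(0))
  }
  data.table::fwrite(lam_tab, file.path(out_dir, "fig6_lambda.csv"))

  comparison <- data.table::copy(herd)
  if (model_realizations > 0L) {
    st <- sweep_counts("full", config_geometry(config), config_fd(config),
                       config_emg(config), comparison$N,
                       model_realizations, config$seed)
    comparison[, model_p_empty_b := st$p_empty_b]
    comparison[, model_mean_n_a := st$mean_n_a]
  }
  data.table::fwrite(comparison, file.path(out_dir, "fig7_comparison.csv"))

  metrics <- list(
    provenance = .provenance(config),
    diagram_fit = list(v0_hat = fit$v0_hat, kappa_hat = fit$kappa_hat,
                       r_squared = fit$r_squared, resid_sd = fit$resid_sd,
                       n_points = fit$n_points),
    activation_threshold = occ$activation,
    lambda_p = if (!is.null(lam_fit)) {
      list(mu = lam_fit$params$mu, sigma = lam_fit$params$sigma,
           beta = lam_fit$params$beta,
           mean = emg_mean(lam_fit$params),
           empirical_mode = lam_fit$empirical_mode,
           n_frames_used = attr(series, "frames_used"),
           n_frames_skipped = attr(series, "n_skipped"))
    } else {
      list(n_frames_used = attr(series, "frames_used"),
           n_frames_skipped = attr(series, "n_skipped"))
    },
    flow = if (!is.null(flow)) list(
      max_rel_gap = flow$max_rel_gap,
      equal_sections_assumed = flow$equal_sections_assumed) else NULL,
    herding = list(N = herd$N, p_empty_b = herd$p_empty_b),
    model_reference = list(
      deterministic_activation_threshold = activation_threshold_deterministic(
        config_geometry(config), config_fd(config),
        lambda = config_lambda_fixed(config)),
      lambda_fixed = config_lambda_fixed(config))
  )
  .write_json(metrics, file.path(out_dir, "metrics.json"))
  invisible(list(records = records, occupancy = occ, fit = fit,
                 global_diagram = gd, lambda_series = series,
                 lambda_fit = lam_fit, flow = flow, herding = herd,
                 comparison = comparison, metrics = metrics))
}
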
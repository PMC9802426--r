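#' Default run configuration
#'
#' Sectioned configuration with the study's printed parameter values:
#' fundamental diagram `v0 = 1.012` m/s, `kappa = 0.017` m/s/ped, velocity
#' noise sd `0.15` m/s; the perceived-ratio EMG both as fitted to data
#' (0.77, 0.30, 0.68) and as tuned for the routing simulations
#' (1.15, 0.20, 0.33); geometry ratio 1.35 with reference area 15 m^2. The
#' `perception$active` switch selects which EMG set drives simulations;
#' `deterministic_ratio: NULL` means the fixed ratio of the deterministic and
#' velocity-noise variants defaults to the active EMG's mean.
#'
#' @return A list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(lambda_g = 1.35, L_A = 1.0, A_ref = 15.0),
    diagram = list(v0 = 1.012, kappa = 0.017, sigma_eps = 0.15, v_min = 0.1),
    perception = list(
      data_fit = list(mu = 0.77, sigma = 0.30, beta = 0.68),
      tuned = list(mu = 1.15, sigma = 0.20, beta = 0.33),
      active = "tuned",
      deterministic_ratio = NULL),
    sweep = list(n_min = 1L, n_max = 30L, realizations = 10000L,
                 variants = c("deterministic", "velocity_noise", "full")),
    dataset = list(n_frames = 50000L,
                   count_law = list(type = "uniform", min = 1L, max = 25L),
                   measurement_sd = 0.05),
    seed = 20221L
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A configuration list.
#' @return The validated config (classed `run_config`), or an error.
#' @export
validate_config <- function(config) {
  need <- c("geometry", "diagram", "perception", "sweep", "dataset", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  with(config, {
    if (geometry$lambda_g <= 0 || geometry$A_ref <= 0 || geometry$L_A <= 0)
      stop("geometry: lambda_g, L_A and A_ref must be positive")
    if (diagram$v0 <= 0 || diagram$kappa < 0 || diagram$sigma_eps < 0)
      stop("diagram: need v0 > 0, kappa >= 0, sigma_eps >= 0")
    for (nm in c("data_fit", "tuned")) {
      p <- perception[[nm]]
      if (p$sigma <= 0 || p$beta <= 0)
        stop("perception$", nm, ": sigma and beta must be positive")
    }
    if (!perception$active %in% c("data_fit", "tuned"))
      stop("perception$active must be 'data_fit' or 'tuned'")
    if (sweep$realizations < 1) stop("sweep: realizations must be >= 1")
    if (sweep$n_min < 0 || sweep$n_max < sweep$n_min)
      stop("sweep: need 0 <= n_min <= n_max")
    if (!all(sweep$variants %in% .variants))
      stop("sweep: unknown variant(s)")
    if (dataset$n_frames < 0) stop("dataset: n_frames must be >= 0")
    if (dataset$measurement_sd < 0)
      stop("dataset: measurement_sd must be >= 0")
  })
  if (!is.numeric(config$seed) || !is.finite(config$seed))
    stop("seed must be a finite number")
  structure(config, class = "run_config")
}

#' Read / write a configuration file
#'
#' YAML with the same sectioned layout as [default_config()]; the round trip
#' is lossless.
#'
#' @param path File path.
#' @return `read_config()` returns a validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `run_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration (provenance stamp)
#'
#' MD5 of the canonical YAML serialization; embedded in every output file so
#' results can be traced to the exact parameters and seed that produced them.
#'
#' @param config A `run_config` list.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Build model objects from a configuration
#'
#' @param config A `run_config` list.
#' @return `config_fd()`: a [fundamental_diagram()]; `config_geometry()`: a
#'   [geometry()]; `config_emg()`: [emg_parameters()] of the requested set;
#'   `config_lambda_fixed()`: the fixed ratio used by the non-full variants
#'   (the explicit override, or the active EMG's mean).
#' @export
config_fd <- function(config) {
  fundamental_diagram(config$diagram$v0, config$diagram$kappa,
                      config$diagram$sigma_eps,
                      config$diagram$v_min %||% 0.1)
}

#' @rdname config_fd
#' @export
config_geometry <- function(config) {
  geometry(config$geometry$lambda_g, config$geometry$L_A,
           config$geometry$A_ref)
}

#' @rdname config_fd
#' @param which `"data_fit"`, `"tuned"`, or `"active"` (the configured set).
#' @export
config_emg <- function(config, which = "active") {
  if (which == "active") which <- config$perception$active
  p <- config$perception[[which]]
  emg_parameters(p$mu, p$sigma, p$beta)
}

#' @rdname config_fd
#' @export
config_lambda_fixed <- function(config) {
  config$perception$deterministic_ratio %||% emg_mean(config_emg(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
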
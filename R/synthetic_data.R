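#' Manifest for a synthetic frame-level tracking dataset
#'
#' Fully determines a synthetic dataset given its seed: number of frames, the
#' law of the per-frame global count, the generating model parameters, and the
#' speed measurement noise. Frames are drawn independently, emulating the
#' decorrelated subsampling applied to real camera footage before frame-level
#' statistics are computed.
#'
#' @param n_frames Number of frames (>= 0).
#' @param fd Generating [fundamental_diagram()].
#' @param emg Generating [emg_parameters()] of the perceived ratio.
#' @param geom A [geometry()].
#' @param seed Integer seed.
#' @param count_law Per-frame global count law: `list(type = "uniform", min,
#'   max)` (default 1..25, covering both sides of the activation threshold) or
#'   `list(type = "fixed", value)`.
#' @param measurement_sd Standard deviation (m/s) of the measurement noise
#'   added to recorded speeds, independent of the behavioral velocity noise;
#'   the diagram-fit residual sd is then about
#'   `sqrt(sigma_eps^2 + measurement_sd^2)`.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(n_frames, fd, emg, geom, seed,
                             count_law = list(type = "uniform",
                                              min = 1L, max = 25L),
                             measurement_sd = 0.05) {
  stopifnot(inherits(fd, "fundamental_diagram"),
            inherits(geom, "geometry"))
  emg <- .check_emg(emg)
  if (!is.numeric(n_frames) || n_frames < 0)
    stop("'n_frames' must be a nonnegative count")
  if (is.null(count_law$type) ||
      !count_law$type %in% c("uniform", "fixed"))
    stop("unknown count law type; use \"uniform\" or \"fixed\"")
  if (count_law$type == "uniform") {
    if (is.null(count_law$min) || is.null(count_law$max) ||
        count_law$min < 0 || count_law$max < count_law$min)
      stop("uniform count law needs 0 <= min <= max")
  } else {
    if (is.null(count_law$value) || count_law$value < 0)
      stop("fixed count law needs a nonnegative 'value'")
  }
  if (!is.numeric(measurement_sd) || measurement_sd < 0)
    stop("'measurement_sd' must be nonnegative")
  structure(list(n_frames = as.integer(n_frames), fd = fd, emg = emg,
                 geom = geom, seed = as.integer(seed),
                 count_law = count_law, measurement_sd = measurement_sd),
            class = "dataset_manifest")
}

.draw_counts <- function(law, n_frames) {
  switch(law$type,
         uniform = sample(seq.int(law$min, law$max), n_frames, replace = TRUE),
         fixed = rep(as.integer(law$value), n_frames))
}

#' Generate synthetic frames
#'
#' For each frame: draw the global count from the manifest's count law, draw a
#' shared perceived ratio (positively truncated EMG) and per-pedestrian
#' velocity noise, route the crowd with the exact discomfort minimizer, and
#' record each pedestrian's speed from the fundamental diagram at the realized
#' occupancy of its path with additive Gaussian velocity noise, plus
#' independent measurement noise.
#'
#' The anticipated speed deviation that drives a pedestrian's route choice and
#' the instantaneous fluctuation of its recorded speed are modeled as
#' independent draws from the same law (Gaussian, sd `fd$sigma_eps`). The
#' routing otherwise selects systematically slow walkers onto the
#' under-occupied path, which would bias any density-speed regression on the
#' recorded speeds at every sample size.
#'
#' @param manifest A [dataset_manifest()].
#' @return A `data.table` of frame records with columns `frame_id`, `ped_id`,
#'   `path`, `speed`, `x`, `y` (`x`/`y` are `NA` until filled by
#'   [generate_positions()]). Zero-pedestrian frames contribute no rows.
#' @export
generate_frames <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  set.seed(manifest$seed)
  fd <- manifest$fd
  geom <- manifest$geom
  nf <- manifest$n_frames
  if (nf == 0L) return(.empty_records())
  counts <- .draw_counts(manifest$count_law, nf)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    n <- counts[f]
    if (n == 0L) next
    eps <- rnorm(n, 0, fd$sigma_eps)
    lp <- remg_positive(1L, manifest$emg)
    sol <- minimize_exact(geom, fd, eps, lp)
    n_own <- ifelse(sol$labels == "A", sol$n_a, sol$n_b)
    v <- individual_velocity(fd, n_own, rnorm(n, 0, fd$sigma_eps)) +
      rnorm(n, 0, manifest$measurement_sd)
    out[[f]] <- data.table::data.table(
      frame_id = f, ped_id = seq_len(n), path = sol$labels,
      speed = pmax(v, 1e-3))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_records())
  rec <- data.table::rbindlist(out)
  rec[, `:=`(x = NA_real_, y = NA_real_)]
  rec[]
}

.empty_records <- function() {
  data.table::data.table(frame_id = integer(0), ped_id = integer(0),
                         path = character(0), speed = numeric(0),
                         x = numeric(0), y = numeric(0))
}

#' Template centerlines of the two paths
#'
#' Path A is a straight segment of length `L_A` along the x axis. Path B is a
#' circular arc over the same chord whose arc length is `lambda_g * L_A`; the
#' opening angle solves `theta / (2 sin(theta/2)) = lambda_g`. For
#' `lambda_g = 1` both templates coincide with the straight segment.
#'
#' @param geom A [geometry()].
#' @param which `"A"` or `"B"`.
#' @param t Arc-length fractions in \[0, 1\].
#' @return A matrix with columns `x`, `y` of points along the template.
#' @export
path_template <- function(geom, which = c("A", "B"), t) {
  which <- match.arg(which)
  stopifnot(all(t >= 0 & t <= 1))
  L <- geom$L_A
  if (which == "A" || geom$lambda_g <= 1 + 1e-9) {
    return(cbind(x = t * L, y = rep(0, length(t))))
  }
  lg <- geom$lambda_g
  theta <- uniroot(function(th) th / (2 * sin(th / 2)) - lg,
                   lower = 1e-8, upper = 2 * pi - 1e-6, tol = 1e-12)$root
  r <- L / (2 * sin(theta / 2))
  yc <- -r * cos(theta / 2)
  alpha <- atan2(-yc, -L / 2)  # angle from center to the (0,0) endpoint
  phi <- alpha - t * theta
  cbind(x = L / 2 + r * cos(phi), y = yc + r * sin(phi))
}

#' Fill record positions along the path templates
#'
#' Cosmetic kinematics: each pedestrian is placed at a uniformly drawn
#' arc-length fraction of its path's template centerline (straight for A,
#' circular arc for B with arc/chord ratio `lambda_g`).
#'
#' @param records A frame-record `data.table` (see [generate_frames()]).
#' @param geom A [geometry()].
#' @param seed Optional integer seed for the position draws.
#' @return The records with `x`, `y` filled.
#' @export
generate_positions <- function(records, geom, seed = NULL) {
  stopifnot(inherits(geom, "geometry"))
  records <- data.table::copy(records)
  if (!nrow(records)) return(records)
  if (!is.null(seed)) set.seed(seed)
  t <- stats::runif(nrow(records))
  ia <- records$path == "A"
  if (any(ia)) {
    pa <- path_template(geom, "A", t[ia])
    records[ia, `:=`(x = pa[, "x"], y = pa[, "y"])]
  }
  if (any(!ia)) {
    pb <- path_template(geom, "B", t[!ia])
    records[!ia, `:=`(x = pb[, "x"], y = pb[, "y"])]
  }
  records[]
}

.frame_header <- c("frame_id", "ped_id", "path", "speed", "x", "y")

#' Write frame records to the CSV dialect
#'
#' Comma-separated, UTF-8, fixed header `frame_id,ped_id,path,speed,x,y`;
#' `path` is `A` or `B`; `x`/`y` are empty strings when absent; speeds are
#' written with 10 significant digits.
#'
#' @param records Frame-record table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(records, path) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  out <- data.table::data.table(
    frame_id = records$frame_id,
    ped_id = records$ped_id,
    path = records$path,
    speed = sprintf("%.10g", records$speed),
    x = fmt(records$x),
    y = fmt(records$y))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read frame records from the CSV dialect
#'
#' Validates the header and every row; malformed rows are reported with their
#' line number (header = line 1). An empty file with only the header yields an
#' empty dataset.
#'
#' @param path Input file path.
#' @return A frame-record `data.table`.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, .frame_header))
    stop("schema error: header must be exactly '",
         paste(.frame_header, collapse = ","), "'")
  dt <- data.table::fread(path, colClasses = list(
    integer = c("frame_id", "ped_id"), character = c("path"),
    numeric = c("speed", "x", "y")), na.strings = "")
  if (!nrow(dt)) return(.empty_records())
  line <- function(i) i + 1L  # header occupies line 1
  bad <- which(!dt$path %in% c("A", "B"))
  if (length(bad))
    stop("malformed row at line ", line(bad[1]),
         ": path must be A or B, got '", dt$path[bad[1]], "'")
  bad <- which(is.na(dt$frame_id) | is.na(dt$ped_id))
  if (length(bad))
    stop("malformed row at line ", line(bad[1]), ": missing frame/ped id")
  bad <- which(!is.finite(dt$speed) | dt$speed <= 0)
  if (length(bad))
    stop("malformed row at line ", line(bad[1]),
         ": speed must be a positive number")
  if (anyDuplicated(dt[, .(frame_id, ped_id)]))
    stop("(frame_id, ped_id) pairs must be unique")
  dt[]
}
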
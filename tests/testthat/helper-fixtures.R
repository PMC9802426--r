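# Study-condition fixtures shared across the suite.

study_fd <- function() fundamental_diagram(1.012, 0.017, 0.15)
study_geom <- function() geometry(lambda_g = 1.35, L_A = 1, A_ref = 15)

# EMG of the perceived ratio as fitted to the tracking data, and as tuned
# for the routing simulations.
emg_data_fit <- function() emg_parameters(0.77, 0.30, 0.68)
emg_tuned <- function() emg_parameters(1.15, 0.20, 0.33)

# Random routing instance: per-pedestrian noise plus a shared perceived ratio.
random_instance <- function(n, fd = study_fd(), emg = emg_tuned()) {
  list(eps = rnorm(n, 0, fd$sigma_eps),
       lambda_p = remg_positive(1L, emg))
}

small_dataset <- function(n_frames = 300, seed = 42,
                          count_law = list(type = "uniform",
                                           min = 1L, max = 25L),
                          fd = study_fd(), emg = emg_tuned(),
                          geom = study_geom(), ...) {
  generate_frames(dataset_manifest(n_frames, fd, emg, geom, seed,
                                   count_law = count_law, ...))
}

# Hand-built records: one frame per row of (n_a, n_b), speeds exactly on the
# noiseless linear diagram unless overridden.
linear_records <- function(splits, v0 = 1.012, kappa = 0.017) {
  rows <- lapply(seq_len(nrow(splits)), function(f) {
    n_a <- splits$n_a[f]; n_b <- splits$n_b[f]
    path <- c(rep("A", n_a), rep("B", n_b))
    n_j <- c(rep(n_a, n_a), rep(n_b, n_b))
    data.frame(frame_id = f, ped_id = seq_len(n_a + n_b), path = path,
               speed = v0 - kappa * n_j, x = NA_real_, y = NA_real_)
  })
  data.table::rbindlist(rows)
}
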
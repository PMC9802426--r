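test_that("manifests validate their count law and determine the dataset", {
  fd <- study_fd(); geom <- study_geom(); emg <- emg_tuned()
  expect_error(dataset_manifest(10, fd, emg, geom, 1,
                                count_law = list(type = "weird")),
               "count law")
  expect_error(dataset_manifest(10, fd, emg, geom, 1,
                                count_law = list(type = "uniform",
                                                 min = 5, max = 2)),
               "min <= max")
  a <- small_dataset(200, seed = 9)
  b <- small_dataset(200, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, small_dataset(200, seed = 10)))
})

test_that("generated frames satisfy the record invariants", {
  rec <- small_dataset(300, seed = 14)
  expect_true(all(rec$speed > 0))
  expect_identical(anyDuplicated(rec[, c("frame_id", "ped_id")]), 0L)
  fs <- frame_summaries(rec)
  expect_true(all(fs$n_a + fs$n_b == fs$N))
  # count law bounds respected
  expect_true(all(fs$N >= 1 & fs$N <= 25))

  # a point mass at N = 0 produces an empty dataset
  empty <- small_dataset(50, seed = 1,
                         count_law = list(type = "fixed", value = 0))
  expect_identical(nrow(empty), 0L)
})

test_that("the short path dominates at low density", {
  rec <- small_dataset(1500, seed = 77)
  fs <- frame_summaries(rec)
  low <- fs[fs$N < 10, ]
  frac_a <- sum(low$n_a) / sum(low$N)
  expect_gt(frac_a, 0.85)
  expect_lt(frac_a, 1.0)
})

test_that("perceived-ratio series from generated data sits near the generating EMG mean", {
  rec <- small_dataset(3000, seed = 121)
  ser <- lambda_p_series(rec)
  expect_gt(length(ser), 500)
  expect_lt(abs(mean(ser) - emg_mean(emg_tuned())) / emg_mean(emg_tuned()),
            0.10)
})

test_that("path templates have the configured arc-length ratio", {
  t <- seq(0, 1, length.out = 2001)
  arclen <- function(xy) sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))

  g1 <- geometry(lambda_g = 1)
  expect_equal(arclen(path_template(g1, "B", t)),
               arclen(path_template(g1, "A", t)), tolerance = 1e-9)

  g <- geometry(lambda_g = 1.35)
  ratio <- arclen(path_template(g, "B", t)) / arclen(path_template(g, "A", t))
  expect_equal(ratio, 1.35, tolerance = 1e-6)

  rec <- small_dataset(100, seed = 5)
  rec <- generate_positions(rec, g, seed = 6)
  expect_true(all(is.finite(rec$x) & is.finite(rec$y)))
  # A-records stay on the straight corridor centerline
  expect_true(all(abs(rec$y[rec$path == "A"]) < 1e-12))
  expect_true(all(rec$y[rec$path == "B"] >= -1e-12))
})

test_that("CSV round trip is lossless and malformed input is rejected with line numbers", {
  rec <- generate_positions(small_dataset(120, seed = 31), study_geom(),
                            seed = 32)
  tf <- tempfile(fileext = ".csv")
  write_frames(rec, tf)
  back <- read_frames(tf)
  expect_identical(back$frame_id, rec$frame_id)
  expect_identical(back$path, rec$path)
  expect_equal(back$speed, rec$speed, tolerance = 1e-9)
  expect_equal(back$x, rec$x, tolerance = 1e-9)

  # header-only file: empty dataset, no error
  writeLines("frame_id,ped_id,path,speed,x,y", tf)
  expect_identical(nrow(read_frames(tf)), 0L)

  # missing column
  writeLines(c("frame_id,ped_id,speed,x,y", "1,1,1.0,,"), tf)
  expect_error(read_frames(tf), "header")

  # bad path label, with its line number
  writeLines(c("frame_id,ped_id,path,speed,x,y",
               "1,1,A,1.0,,", "1,2,Q,1.0,,"), tf)
  expect_error(read_frames(tf), "line 3")

  # nonpositive speed
  writeLines(c("frame_id,ped_id,path,speed,x,y", "1,1,A,-0.2,,"), tf)
  expect_error(read_frames(tf), "positive")

  # duplicate (frame, pedestrian)
  writeLines(c("frame_id,ped_id,path,speed,x,y",
               "1,1,A,1.0,,", "1,1,B,0.9,,"), tf)
  expect_error(read_frames(tf), "unique")
})
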
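test_that("series CSV write/read round trip is lossless", {
  ds <- generate_dataset(tiny_design(c(10, 100), reps = 2, duration = 20),
                         kinetic_params(), seed = 6)
  f <- tempfile(fileext = ".csv")
  write_series_csv(ds, f)
  back <- read_series_csv(f)
  expect_length(back, length(ds))
  for (i in seq_along(ds)) {
    expect_equal(back[[i]]$values, ds[[i]]$values, tolerance = 1e-12)
    expect_equal(back[[i]]$tube_id, ds[[i]]$tube_id)
    expect_equal(back[[i]]$true_concentration, ds[[i]]$true_concentration)
    expect_equal(back[[i]]$sampling_interval_s, ds[[i]]$sampling_interval_s)
  }
})

test_that("malformed CSV inputs produce named validation errors", {
  f <- tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_series_csv(f), "empty")

  writeLines(c("tube_id,concentration,time_s,channel,intensity",
               "t1,10,0,R,0.5", "t1,10,0,G,0.5", "t1,10,1,R,0.4"), f)
  expect_error(read_series_csv(f), "ragged")

  writeLines(c("tube_id,time_s,channel,intensity", "t1,0,R,0.5"), f)
  expect_error(read_series_csv(f), "concentration")

  writeLines(c("tube_id,concentration,time_s,channel,intensity",
               "t1,10,0,R,abc"), f)
  expect_error(read_series_csv(f), "intensit")
})

test_that("rendered frames round-trip through ROI extraction", {
  p0 <- kinetic_params(noise_sd = 0, replicate_amplitude_cv = 0)
  s <- generate_dataset(tiny_design(650, reps = 1, duration = 20), p0,
                        seed = 1)[[1]]
  d <- file.path(tempdir(), "frames_rt")
  unlink(d, recursive = TRUE)
  render_frames(s, d, width = 32, height = 24, roi = roi_spec(8, 6, 24, 18))
  expect_length(list.files(d, pattern = "\\.png$"), 20)
  back <- extract_series_from_frames(d)
  # 8-bit quantisation bounds the round-trip error by half a grey step
  expect_lt(max(abs(back$values - s$values)), 0.5 / 255 + 1e-9)
  expect_equal(back$true_concentration, s$true_concentration)
  expect_equal(back$sampling_interval_s, s$sampling_interval_s)
})

test_that("a constant series renders identical frames", {
  s <- make_series(matrix(0.25, 3, 4), id = "const")
  d <- file.path(tempdir(), "frames_const")
  unlink(d, recursive = TRUE)
  render_frames(s, d, width = 16, height = 16, roi = roi_spec(2, 2, 10, 10))
  sums <- tools::md5sum(list.files(d, pattern = "png$", full.names = TRUE))
  expect_length(unique(unname(sums)), 1)
})

test_that("frame order is lexicographic by filename, not file time", {
  d <- file.path(tempdir(), "frames_order")
  unlink(d, recursive = TRUE)
  dir.create(d)
  # write frames in reverse order so mtimes contradict filenames
  for (v in c(3, 2, 1))
    png::writePNG(array(v / 10, c(8, 8, 3)),
                  file.path(d, sprintf("frame_%05d.png", v)))
  s <- extract_series_from_frames(d, roi = roi_spec(0, 0, 8, 8),
                                  frame_rate_hz = 1)
  expect_equal(unname(s$values[1, ]), c(1, 2, 3) / 10, tolerance = 1e-2)
})

test_that("single uniform grey frame yields one timepoint with equal channels", {
  d <- file.path(tempdir(), "frames_grey")
  unlink(d, recursive = TRUE)
  dir.create(d)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(d, "only.png"))
  s <- extract_series_from_frames(d, roi = roi_spec(1, 1, 7, 7),
                                  frame_rate_hz = 2)
  expect_equal(ncol(s$values), 1)
  expect_equal(s$sampling_interval_s, 0.5)
  expect_true(all(abs(s$values - s$values[1, 1]) < 1e-9))
})

test_that("inconsistent frame dimensions and bad ROIs are rejected", {
  d <- file.path(tempdir(), "frames_bad")
  unlink(d, recursive = TRUE)
  dir.create(d)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(d, "a.png"))
  png::writePNG(array(0.5, c(6, 8, 3)), file.path(d, "b.png"))
  expect_error(extract_series_from_frames(d, roi = roi_spec(0, 0, 4, 4),
                                          frame_rate_hz = 1),
               "dimensions")
  expect_error(roi_spec(4, 0, 4, 4), "x0 < x1")
  s <- make_series(matrix(0.5, 3, 2))
  expect_error(render_frames(s, tempfile(), width = 16, height = 16,
                             roi = roi_spec(0, 0, 20, 10)),
               "exceeds image bounds")
})
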
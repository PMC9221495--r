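fake_predictions <- function(true, pred) {
  structure(data.frame(
    tube_id = paste0("t", seq_along(true)),
    true_concentration = true,
    predicted_concentration = pred,
    nearest_neighbor = paste0("n", seq_along(true)),
    distance = abs(pred - true) / 1000,
    stringsAsFactors = FALSE),
    class = c("assay_predictions", "data.frame"))
}

design_grid <- c(1.5, 3, 6.5, 17, 33, 45, 65,
                100, 200, 350, 500, 600, 700, 900, 1000, 1100, 1200)

test_that("perfect predictions give zero errors and full exact rate", {
  p <- fake_predictions(design_grid, design_grid)
  r <- summarize_predictions(p, design_grid)
  expect_equal(r$overall_max_relative_error, 0)
  expect_equal(r$neighbor_violations, 0)
  expect_equal(r$exact_assignment_rate, 1)
  expect_equal(sum(r$per_level$n), r$n_predictions)
})

test_that("relative error and grid distance follow the design grid", {
  # 1000 predicted as 900: 10% relative error, adjacent level, no violation
  p <- fake_predictions(c(1000, 100), c(900, 350))
  r <- summarize_predictions(p, design_grid)
  expect_equal(r$overall_max_relative_error, 2.5)  # |350-100|/100
  lev1000 <- r$per_level[r$per_level$true_concentration == 1000, ]
  expect_equal(lev1000$max_relative_error, 0.1)
  # 100 -> 350 spans two grid positions: a neighbour violation
  expect_equal(r$neighbor_violations, 1)
  expect_equal(r$exact_assignment_rate, 0)
})

test_that("per-level means and SDs aggregate that level's predictions", {
  p <- fake_predictions(c(200, 200, 200, 100), c(200, 350, 100, 100))
  r <- summarize_predictions(p, design_grid)
  l200 <- r$per_level[r$per_level$true_concentration == 200, ]
  expect_equal(l200$n, 3)
  expect_equal(l200$mean_predicted, mean(c(200, 350, 100)))
  expect_equal(l200$sd_predicted, sd(c(200, 350, 100)))
  expect_equal(l200$mean_relative_error, mean(c(0, 150, 100) / 200))
  expect_equal(r$overall_max_relative_error,
               max(r$per_level$max_relative_error, na.rm = TRUE))
})

test_that("a zero true level is reported by absolute error", {
  p <- fake_predictions(c(0, 0, 10), c(0, 10, 10))
  r <- summarize_predictions(p, c(0, 10, 100))
  l0 <- r$per_level[r$per_level$true_concentration == 0, ]
  expect_true(is.na(l0$max_relative_error))
  expect_equal(l0$mean_absolute_error, 5)
  expect_equal(r$overall_max_relative_error, 0)  # the 10-level is exact
})

test_that("unknown true levels are rejected", {
  p <- fake_predictions(c(123), c(100))
  expect_error(summarize_predictions(p, design_grid), "not on the grid")
})

test_that("calibration plots are written for full and single-level reports", {
  p <- fake_predictions(rep(design_grid, each = 2),
                        rep(design_grid, each = 2) * c(1, 1.05))
  r <- summarize_predictions(p, design_grid)
  f <- tempfile(fileext = ".png")
  plot_calibration_file(r, f)
  expect_true(file.exists(f) && file.size(f) > 0)

  r1 <- summarize_predictions(fake_predictions(100, 100), design_grid)
  f2 <- tempfile(fileext = ".png")
  plot_calibration_file(r1, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})

test_that("report export round-trips through JSON and CSV", {
  p <- fake_predictions(c(100, 200), c(100, 200))
  r <- summarize_predictions(p, design_grid)
  j <- tempfile(fileext = ".json")
  write_report(r, j)
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(back$exact_assignment_rate, 1)
  expect_equal(nrow(back$per_level), 2)
  cs <- tempfile(fileext = ".csv")
  write_report(r, cs)
  expect_equal(nrow(read.csv(cs)), 2)
})
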
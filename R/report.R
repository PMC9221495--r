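#' Summarise leave-one-out predictions per concentration level
#'
#' Computes the per-level mean and standard deviation of the predicted
#' concentration, per-tube relative errors (|predicted - true| / true; at a
#' true concentration of 0 the relative error is undefined and the absolute
#' error is reported instead), the exact-assignment rate, and the count of
#' neighbour-level violations — predictions more than one position away
#' from the truth on the sorted design grid.
#'
#' @param predictions An `assay_predictions` data.frame (from
#'   [loo_evaluate()] or [predict.dtw_knn()]) with known true
#'   concentrations.
#' @param level_grid Sorted concentration grid; defaults to the distinct
#'   true concentrations in `predictions`. Every true level must be on the
#'   grid.
#' @return An object of class `assay_eval`: a list with a `per_level`
#'   data.frame (`true_concentration`, `n`, `mean_predicted`,
#'   `sd_predicted`, `mean_relative_error`, `max_relative_error`), and
#'   scalars `overall_max_relative_error`, `neighbor_violations`,
#'   `exact_assignment_rate`, `n_predictions`.
#' @export
summarize_predictions <- function(predictions, level_grid = NULL) {
  df <- as.data.frame(predictions)
  if (nrow(df) == 0) stop_invalid("no predictions to summarise")
  if (any(is.na(df$true_concentration)))
    stop_invalid("summary requires known true concentrations")
  if (is.null(level_grid))
    level_grid <- sort(unique(df$true_concentration))
  level_grid <- sort(as.numeric(level_grid))
  unknown <- setdiff(unique(df$true_concentration), level_grid)
  if (length(unknown))
    stop_invalid("true level(s) not on the grid: %s",
                 paste(unknown, collapse = ", "))

  true_idx <- match(df$true_concentration, level_grid)
  # predicted levels may legitimately be off-grid when predictions come from
  # a model trained on a different grid; index distance then counts from the
  # nearest grid position
  pred_idx <- match(df$predicted_concentration, level_grid)
  off <- is.na(pred_idx)
  if (any(off))
    pred_idx[off] <- vapply(df$predicted_concentration[off], function(p)
      which.min(abs(level_grid - p)), integer(1))
  grid_dist <- abs(pred_idx - true_idx)

  err <- abs(df$predicted_concentration - df$true_concentration)
  rel <- ifelse(df$true_concentration > 0, err / df$true_concentration, NA)

  per <- lapply(sort(unique(df$true_concentration)), function(lv) {
    sel <- df$true_concentration == lv
    r <- rel[sel]
    data.frame(true_concentration = lv,
               n = sum(sel),
               mean_predicted = mean(df$predicted_concentration[sel]),
               sd_predicted = if (sum(sel) > 1)
                 sd(df$predicted_concentration[sel]) else 0,
               mean_relative_error = if (lv > 0) mean(r) else NA_real_,
               max_relative_error = if (lv > 0) max(r) else NA_real_,
               mean_absolute_error = mean(err[sel]))
  })
  per <- do.call(rbind, per)
  structure(
    list(per_level = per,
         level_grid = level_grid,
         overall_max_relative_error =
           if (all(is.na(rel))) NA_real_ else max(rel, na.rm = TRUE),
         neighbor_violations = sum(grid_dist > 1),
         exact_assignment_rate =
           mean(df$predicted_concentration == df$true_concentration),
         n_predictions = nrow(df)),
    class = "assay_eval")
}

#' @export
print.assay_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Leave-one-out evaluation of %d predictions\n", x$n_predictions))
  cat(sprintf("  exact assignment rate: %.1f%%\n",
              100 * x$exact_assignment_rate))
  cat(sprintf("  max per-tube relative error: %s%%\n",
              format(100 * x$overall_max_relative_error, digits = digits)))
  cat(sprintf("  neighbour-level violations (>1 grid position off): %d\n",
              x$neighbor_violations))
  cat("\nPer level:\n")
  print(format(x$per_level, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summary method for a fitted DTW k-NN quantifier
#'
#' Runs [loo_evaluate()] and summarises the predictions with
#' [summarize_predictions()].
#'
#' @param object A fitted [dtw_knn()] model.
#' @param ... Unused.
#' @return An `assay_eval` object.
#' @export
summary.dtw_knn <- function(object, ...) {
  summarize_predictions(loo_evaluate(object), level_grid = object$levels)
}

#' Calibration plot: mean prediction vs true concentration
#'
#' Scatter of the per-level mean predicted concentration against the true
#' concentration with standard-deviation bars and the identity reference
#' line, on log-log axes (the design grid spans almost three decades).
#'
#' @param x An `assay_eval` object.
#' @param log Axis log specification passed to [graphics::plot()];
#'   `"xy"` by default, use `""` for linear axes.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.assay_eval <- function(x, log = "xy", ...) {
  p <- x$per_level
  if (nrow(p) == 0) stop_invalid("empty report")
  lo <- pmax(p$mean_predicted - p$sd_predicted, .Machine$double.eps)
  hi <- p$mean_predicted + p$sd_predicted
  rng <- range(p$true_concentration, lo, hi)
  graphics::plot(p$true_concentration, p$mean_predicted, log = log,
                 xlim = rng, ylim = rng,
                 xlab = "True concentration", ylab = "Predicted concentration",
                 pch = 19, ...)
  graphics::abline(0, 1, col = "red", untf = TRUE)
  has_bar <- p$sd_predicted > 0
  if (any(has_bar))
    graphics::arrows(p$true_concentration[has_bar], lo[has_bar],
                     p$true_concentration[has_bar], hi[has_bar],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Write a calibration figure to file
#'
#' @param report An `assay_eval` object.
#' @param out Output path; format from the extension (png or svg).
#' @param width,height Figure size in pixels (png) or inches (svg).
#' @param ... Passed to [plot.assay_eval()].
#' @return `out`, invisibly.
#' @export
plot_calibration_file <- function(report, out, width = 800, height = 600,
                                  ...) {
  stopifnot(inherits(report, "assay_eval"))
  if (nrow(report$per_level) == 0) stop_invalid("empty report")
  ext <- tolower(tools::file_ext(out))
  if (ext == "svg") grDevices::svg(out, width = width / 100,
                                   height = height / 100)
  else grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(report, ...)
  invisible(out)
}

#' Export an evaluation report
#'
#' @param report An `assay_eval` object.
#' @param path Output path; `.json` writes the whole report, `.csv` the
#'   per-level table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assay_eval"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  } else {
    write.csv(report$per_level, path, row.names = FALSE)
  }
  invisible(path)
}
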
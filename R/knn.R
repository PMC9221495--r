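#' Fit a DTW nearest-neighbour concentration quantifier
#'
#' The central model of the package: a k-nearest-neighbour classifier over
#' the concentration grid, using the channel-averaged dynamic time warping
#' distance between block-averaged kinetic colour traces. Fitting stores the
#' preprocessed training series; prediction assigns a query to the label of
#' its nearest training tube (k = 1 by default, as appropriate for small
#' replicated calibration sets). Ties in distance are broken towards the
#' lower concentration, a deterministic and conservative rule for
#' contamination screening.
#'
#' @param data A `color_ts_list` of labelled training series (e.g. from
#'   [generate_dataset()] or [read_series_csv()]); every series needs a
#'   known `true_concentration`.
#' @param k Number of neighbours (default 1); must be smaller than the
#'   training-set size.
#' @param dtw A [dtw_config()].
#' @param preprocess A [preprocess_config()], applied identically to
#'   training series and queries; `NULL` to skip preprocessing.
#' @return An object of class `dtw_knn` with methods [predict.dtw_knn()],
#'   [summary.dtw_knn()], [residuals.dtw_knn()] and `print()`.
#' @examples
#' ds <- generate_dataset(default_design(), kinetic_params(), seed = 1)
#' fit <- dtw_knn(ds)
#' fit
#' @export
dtw_knn <- function(data, k = 1, dtw = dtw_config(),
                    preprocess = preprocess_config()) {
  stopifnot(inherits(dtw, "dtw_config"))
  if (!is.list(data) || length(data) < 2)
    stop_invalid("training data must contain >= 2 series")
  data <- new_color_ts_list(data)
  labels <- concentrations_of(data)
  if (any(is.na(labels)))
    stop_invalid("all training series need a known concentration")
  check_number(k, "k", 1)
  if (k != round(k)) stop_invalid("'k' must be an integer")
  if (k >= length(data))
    stop_invalid("k = %d must be smaller than the training-set size (%d)",
                 k, length(data))
  prep <- if (is.null(preprocess)) data else block_average(data, preprocess)
  structure(
    list(training = prep,
         raw = data,
         labels = labels,
         levels = sort(unique(labels)),
         k = as.integer(k),
         dtw = dtw,
         preprocess = preprocess),
    class = "dtw_knn")
}

#' @export
print.dtw_knn <- function(x, ...) {
  cat(sprintf("DTW %d-NN concentration quantifier\n", x$k))
  cat(sprintf("  %d training tubes over %d levels: %s\n",
              length(x$training), length(x$levels),
              paste(x$levels, collapse = ", ")))
  print(x$dtw)
  if (!is.null(x$preprocess)) print(x$preprocess)
  invisible(x)
}

# rank training indices by (distance, label); deterministic under input
# permutation because ties resolve on concentration, never position
rank_neighbors <- function(dists, labels) {
  order(dists, labels)
}

knn_vote <- function(dists, labels, k) {
  ord <- rank_neighbors(dists, labels)
  top <- ord[seq_len(k)]
  if (k == 1L) return(list(pred = labels[top], neighbors = top))
  votes <- table(labels[top])
  best <- names(votes)[votes == max(votes)]
  if (length(best) == 1L) {
    pred <- as.numeric(best)
  } else {
    # tie between modes: smallest distance among tied labels, then lowest
    cand <- as.numeric(best)
    first_dist <- vapply(cand, function(l) min(dists[top][labels[top] == l]),
                         numeric(1))
    pred <- min(cand[first_dist == min(first_dist)])
  }
  list(pred = pred, neighbors = top)
}

#' Predict concentrations for new kinetic traces
#'
#' Applies the model's preprocessing to each query, computes the
#' channel-averaged DTW distance to every training tube and assigns the
#' k-nearest-neighbour label.
#'
#' @param object A fitted [dtw_knn()] model.
#' @param newdata A `color_ts` or `color_ts_list` of queries.
#' @param ... Unused.
#' @return A data.frame of class `assay_predictions` with one row per query:
#'   `tube_id`, `true_concentration` (NA if unknown),
#'   `predicted_concentration`, `nearest_neighbor`, `distance`, plus
#'   list-columns `neighbor_ids` and `neighbor_distances` holding the k
#'   nearest neighbours in non-decreasing distance order.
#' @export
predict.dtw_knn <- function(object, newdata, ...) {
  if (inherits(newdata, "color_ts"))
    newdata <- new_color_ts_list(list(newdata))
  if (length(newdata) == 0)
    stop_invalid("no query series supplied")
  prep <- if (is.null(object$preprocess)) new_color_ts_list(newdata) else
    block_average(newdata, object$preprocess)
  ids <- vapply(object$training, function(s) s$tube_id, character(1))
  rows <- lapply(seq_along(prep), function(qi) {
    q <- prep[[qi]]
    d <- vapply(object$training, function(tr)
      multichannel_distance(q, tr, object$dtw), numeric(1))
    v <- knn_vote(d, object$labels, object$k)
    nb <- v$neighbors
    list(tube_id = q$tube_id,
         true_concentration = q$true_concentration,
         predicted_concentration = v$pred,
         nearest_neighbor = ids[nb[1]],
         distance = d[nb[1]],
         neighbor_ids = ids[nb],
         neighbor_distances = d[nb])
  })
  build_predictions(rows)
}

build_predictions <- function(rows) {
  df <- data.frame(
    tube_id = vapply(rows, `[[`, character(1), "tube_id"),
    true_concentration = vapply(rows, `[[`, numeric(1), "true_concentration"),
    predicted_concentration = vapply(rows, `[[`, numeric(1),
                                     "predicted_concentration"),
    nearest_neighbor = vapply(rows, `[[`, character(1), "nearest_neighbor"),
    distance = vapply(rows, `[[`, numeric(1), "distance"),
    stringsAsFactors = FALSE)
  df$neighbor_ids <- lapply(rows, `[[`, "neighbor_ids")
  df$neighbor_distances <- lapply(rows, `[[`, "neighbor_distances")
  class(df) <- c("assay_predictions", "data.frame")
  df
}

#' Leave-one-out evaluation of a DTW k-NN quantifier
#'
#' Each series is predicted once from all the others, with preprocessing
#' applied identically to query and training tubes. The all-pairs distance
#' matrix is computed once and reused across the folds, which is equivalent
#' to refitting the model without the held-out tube at every fold.
#'
#' @param x A fitted [dtw_knn()] model, or a `color_ts_list` (in which case
#'   a model is fitted first with the remaining arguments).
#' @param ... Passed to [dtw_knn()] when `x` is a dataset.
#' @return An `assay_predictions` data.frame with one row per series, in
#'   input order. The distance matrix is attached as attribute
#'   `"distance_matrix"`.
#' @examples
#' ds <- generate_dataset(default_design(), kinetic_params(), seed = 1)
#' preds <- loo_evaluate(dtw_knn(ds))
#' mean(preds$predicted_concentration == preds$true_concentration)
#' @export
loo_evaluate <- function(x, ...) {
  model <- if (inherits(x, "dtw_knn")) x else dtw_knn(x, ...)
  n <- length(model$training)
  if (n < 2)
    stop_invalid("leave-one-out needs >= 2 series")
  if (model$k >= n - 1 && n > 2)
    stop_invalid("k = %d too large for leave-one-out on %d series",
                 model$k, n)
  M <- distance_matrix(model$training, model$dtw)
  ids <- vapply(model$training, function(s) s$tube_id, character(1))
  rows <- lapply(seq_len(n), function(i) {
    d <- M[i, -i]
    lab <- model$labels[-i]
    v <- knn_vote(d, lab, model$k)
    nb_global <- seq_len(n)[-i][v$neighbors]
    list(tube_id = ids[i],
         true_concentration = model$labels[i],
         predicted_concentration = v$pred,
         nearest_neighbor = ids[nb_global[1]],
         distance = unname(d[v$neighbors[1]]),
         neighbor_ids = ids[nb_global],
         neighbor_distances = unname(d[v$neighbors]))
  })
  out <- build_predictions(rows)
  attr(out, "distance_matrix") <- M
  out
}

#' @export
print.assay_predictions <- function(x, ...) {
  cat(sprintf("<assay_predictions> %d tubes\n", nrow(x)))
  show <- as.data.frame(x)[, c("tube_id", "true_concentration",
                               "predicted_concentration", "distance")]
  print(utils::head(show, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Leave-one-out residuals of a DTW k-NN quantifier
#'
#' @param object A fitted [dtw_knn()] model.
#' @param ... Unused.
#' @return Numeric vector `predicted - true` over the leave-one-out folds,
#'   named by tube id.
#' @export
residuals.dtw_knn <- function(object, ...) {
  p <- loo_evaluate(object)
  setNames(p$predicted_concentration - p$true_concentration, p$tube_id)
}

#' Write predictions to CSV (list-columns flattened)
#'
#' @param predictions An `assay_predictions` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  df <- as.data.frame(predictions)
  df$neighbor_ids <- vapply(df$neighbor_ids, paste, character(1),
                            collapse = ";")
  df$neighbor_distances <- vapply(df$neighbor_distances,
                                  function(v) paste(format(v, digits = 15),
                                                    collapse = ";"),
                                  character(1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tube_id", "true_concentration", "predicted_concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("missing columns in %s: %s", path, paste(miss, collapse = ", "))
  if (!is.null(df$neighbor_ids))
    df$neighbor_ids <- strsplit(as.character(df$neighbor_ids), ";",
                                fixed = TRUE)
  if (!is.null(df$neighbor_distances))
    df$neighbor_distances <- lapply(
      strsplit(as.character(df$neighbor_distances), ";", fixed = TRUE),
      as.numeric)
  class(df) <- c("assay_predictions", "data.frame")
  df
}
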
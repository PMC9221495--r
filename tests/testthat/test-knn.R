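make_labeled_set <- function(n_per_level = 2, levels = c(10, 100, 1000),
                             seed = 1, noise = 0, cv = 0) {
  generate_dataset(tiny_design(levels, n_per_level),
                   kinetic_params(noise_sd = noise,
                                  replicate_amplitude_cv = cv),
                   seed = seed)
}

test_that("an exact copy in the training set is recovered at distance zero", {
  ds <- make_labeled_set(noise = 0.002, cv = 0.01)
  fit <- dtw_knn(ds)
  query <- ds[[3]]
  p <- predict(fit, query)
  expect_equal(p$predicted_concentration, query$true_concentration)
  expect_equal(p$distance, 0)
  expect_equal(p$nearest_neighbor, query$tube_id)
})

test_that("leave-one-out on two series swaps their labels", {
  ds <- make_labeled_set(n_per_level = 1, levels = c(10, 1000))
  p <- loo_evaluate(dtw_knn(ds))
  expect_equal(p$predicted_concentration, rev(p$true_concentration))
  expect_equal(p$nearest_neighbor, rev(p$tube_id))
})

test_that("noise-free leave-one-out recovers every level exactly", {
  ds <- generate_dataset(default_design(),
                         kinetic_params(noise_sd = 0,
                                        replicate_amplitude_cv = 0),
                         seed = 3)
  p <- loo_evaluate(dtw_knn(ds))
  expect_equal(p$predicted_concentration, p$true_concentration)
  expect_true(all(p$distance == 0))
})

test_that("predictions are a closed world over the training levels", {
  ds <- make_labeled_set(noise = 0.01, cv = 0.05, seed = 9)
  p <- loo_evaluate(dtw_knn(ds))
  expect_true(all(p$predicted_concentration %in%
                    unique(p$true_concentration)))
})

test_that("predictions are invariant to dataset permutation", {
  ds <- make_labeled_set(n_per_level = 3, noise = 0.005, cv = 0.02, seed = 2)
  p1 <- loo_evaluate(dtw_knn(ds))
  set.seed(99)
  perm <- sample(length(ds))
  p2 <- loo_evaluate(dtw_knn(ds[perm]))
  m <- match(p1$tube_id, p2$tube_id)
  expect_equal(p1$predicted_concentration, p2$predicted_concentration[m])
  expect_equal(p1$distance, p2$distance[m])
})

test_that("matrix-based leave-one-out equals naive per-query refitting", {
  ds <- make_labeled_set(n_per_level = 2, noise = 0.004, cv = 0.02, seed = 4)
  fit <- dtw_knn(ds)
  p_fast <- loo_evaluate(fit)
  naive <- vapply(seq_along(ds), function(i) {
    model <- dtw_knn(ds[-i])
    predict(model, ds[[i]])$predicted_concentration
  }, numeric(1))
  expect_equal(p_fast$predicted_concentration, naive)
})

test_that("distance ties break towards the lower concentration", {
  # two identical training series with different labels: tie at distance 0
  v <- matrix(seq(0, 1, length.out = 30), 3, 10, byrow = TRUE)
  tr <- structure(list(
    make_series(v, id = "hi", conc = 100),
    make_series(v, id = "lo", conc = 10),
    make_series(v + 5, id = "far", conc = 1000)
  ), class = "color_ts_list")
  fit <- dtw_knn(tr, preprocess = NULL)
  p <- predict(fit, make_series(v, id = "q"))
  expect_equal(p$predicted_concentration, 10)
})

test_that("k > 1 takes the mode of the nearest labels", {
  p0 <- kinetic_params(noise_sd = 0, replicate_amplitude_cv = 0)
  ds <- generate_dataset(tiny_design(c(10, 1000), reps = 3), p0, seed = 1)
  fit <- dtw_knn(ds, k = 3)
  p <- loo_evaluate(fit)
  # with 3 identical same-level replicates, 2 of the 3 nearest share the level
  expect_equal(p$predicted_concentration, p$true_concentration)
  expect_length(p$neighbor_ids[[1]], 3)
  expect_true(all(vapply(p$neighbor_distances,
                         function(d) !is.unsorted(d), TRUE)))
})

test_that("degenerate configurations are rejected", {
  ds <- make_labeled_set()
  expect_error(dtw_knn(ds[1]), ">= 2")
  expect_error(dtw_knn(ds, k = length(ds)), "smaller than")
  unlabeled <- structure(list(make_series(matrix(0, 3, 5)),
                              make_series(matrix(1, 3, 5))),
                         class = "color_ts_list")
  expect_error(dtw_knn(unlabeled, preprocess = NULL), "known concentration")
})
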
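# Independent DTW oracle: explicit enumeration of every monotone,
# contiguous, boundary-anchored warping path from (1,1) to (n,m), taking the
# minimum total local cost. Shares no code with the package's
# dynamic-programming kernel. Paths are cached per (n, m).

.path_cache <- new.env(parent = emptyenv())

enumerate_warping_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- list()
  walk <- function(path, i, j) {
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (i < n) walk(rbind(path, c(i + 1L, j)), i + 1L, j)
    if (j < m) walk(rbind(path, c(i, j + 1L)), i, j + 1L)
    if (i < n && j < m) walk(rbind(path, c(i + 1L, j + 1L)), i + 1L, j + 1L)
  }
  walk(matrix(c(1L, 1L), 1, 2), 1L, 1L)
  .path_cache[[key]] <- paths
  paths
}

dtw_oracle <- function(x, y, squared = FALSE) {
  cost <- if (squared) function(a, b) (a - b)^2 else function(a, b) abs(a - b)
  paths <- enumerate_warping_paths(length(x), length(y))
  min(vapply(paths, function(p)
    sum(cost(x[p[, 1]], y[p[, 2]])), numeric(1)))
}

# small deterministic multichannel fixtures built in code
make_series <- function(values, interval = 1, id = "t", conc = NA_real_,
                        channels = NULL) {
  color_ts(values, interval, tube_id = id, true_concentration = conc,
           channel_names = channels)
}

tiny_design <- function(levels = c(10, 100, 1000), reps = 2,
                        duration = 30) {
  dataset_design(levels = levels, replicates = reps, duration_s = duration,
                 frame_rate_hz = 1)
}
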
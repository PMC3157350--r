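# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# a small generated dataset, cached by (n, seed)
fixture_dataset <- function(n = 60L, seed = 101L) {
  key <- paste0("ds_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(synthetic_config(n_faces = n,
                                                             seed = seed))
  .fixture_env[[key]]
}

fixture_ids <- function(ds) vapply(ds$samples, `[[`, "", "id")
fixture_landmarks <- function(ds) lapply(ds$samples, `[[`, "landmarks")
fixture_scores <- function(ds) {
  m <- t(vapply(ds$samples, function(s) s$scores, numeric(9)))
  rownames(m) <- fixture_ids(ds)
  m
}

# brute-force descriptor length: enumerate the index tuples of the three sets
brute_force_descriptor_length <- function(P) {
  len <- 0L
  for (i in seq_len(P)) len <- len + 2L                    # set 1: (r, a)
  for (i in seq_len(P)) for (j in seq_len(P)) len <- len + 2L  # set 2
  for (i in seq_len(P)) for (j in seq_len(P)) if (i < j) len <- len + 1L
  len
}

# brute-force HOG length: walk the block grid
brute_force_hog_length <- function(params) {
  nc <- params$window %/% params$cell
  stride <- params$block - params$overlap
  count <- 0L
  r <- 1L
  while (r + params$block - 1L <= nc) {
    c_ <- 1L
    while (c_ + params$block - 1L <= nc) {
      count <- count + params$block * params$block * params$n_bins
      c_ <- c_ + stride
    }
    r <- r + stride
  }
  as.integer(count)
}

# brute-force kNN: all-pairs scan with the same tie rules
brute_force_knn <- function(train_x, train_y, test_x, k) {
  t(apply(test_x, 1L, function(z) {
    d <- sqrt(colSums((t(train_x) - z)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    share <- mean(train_y[nb] == 1)
    c(label = if (share > 0.5) 1 else -1, confidence = max(share, 1 - share))
  }))
}

# exhaustive stump search: minimize weighted squared error over all
# features and thresholds (uniform weights)
brute_force_stump <- function(X, y) {
  best <- list(err = Inf)
  n <- nrow(X)
  w <- rep(1 / n, n)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2L) next
    for (t in (xs[-1] + xs[-length(xs)]) / 2) {
      left <- X[, f] <= t
      lv <- sum(w[left] * y[left]) / sum(w[left])
      rv <- sum(w[!left] * y[!left]) / sum(w[!left])
      pred <- ifelse(left, lv, rv)
      err <- sum(w * (y - pred)^2)
      if (err < best$err - 1e-12)
        best <- list(err = err, feature = f, threshold = t,
                     left = lv, right = rv)
    }
  }
  best
}
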
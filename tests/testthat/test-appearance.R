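make_images <- function(n, size = 16, seed = 5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(size * size), size, size))
}

test_that("eigenfaces basics: rank, centering, complete reconstruction", {
  imgs <- make_images(2)
  m <- fit_eigenfaces(imgs, 0.95)
  expect_identical(m$k, 1L)  # two distinct images: rank-1 centered data
  ev <- m$eigenvalues
  expect_gt(ev[1] / sum(ev), 1 - 1e-10)

  imgs <- make_images(8)
  m <- fit_eigenfaces(imgs, 1)
  mean_img <- matrix(m$mean, 16, 16)
  expect_lt(max(abs(project_eigenfaces(m, mean_img))), 1e-10)

  # full basis reconstructs exactly
  x <- imgs[[3]]
  co <- project_eigenfaces(m, x)
  rec <- m$mean + as.vector(m$components %*% co)
  expect_lt(max(abs(rec - as.vector(x))), 1e-8)

  # eigenvector orthonormality and non-increasing eigenvalues
  expect_lt(max(abs(crossprod(m$components) - diag(m$k))), 1e-10)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
})

test_that("projection of mean + c * component recovers (c, 0, ...) and Bessel holds", {
  imgs <- make_images(8, seed = 6)
  m <- fit_eigenfaces(imgs, 0.99)
  comp1 <- matrix(m$components[, 1], 16, 16)
  x <- matrix(m$mean, 16, 16) + 2.5 * comp1
  co <- project_eigenfaces(m, x)
  expect_equal(co[1], 2.5, tolerance = 1e-10)
  expect_lt(max(abs(co[-1])), 1e-10)

  y <- imgs[[1]]
  co <- project_eigenfaces(m, y)
  expect_lte(sum(co^2), sum((as.vector(y) - m$mean)^2) + 1e-8)

  expect_error(fit_eigenfaces(imgs, 0), "config")
  expect_error(project_eigenfaces(m, matrix(0, 4, 4)), "mismatch")
})

test_that("eigen reconstruction error is non-increasing in retained components", {
  imgs <- make_images(10, seed = 8)
  m <- fit_eigenfaces(imgs, 1)
  x <- as.vector(imgs[[2]]) - m$mean
  errs <- vapply(seq_len(m$k), function(k) {
    V <- m$components[, 1:k, drop = FALSE]
    sum((x - V %*% crossprod(V, x))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("HOG length matches brute-force block enumeration", {
  expect_identical(hog_length(hog_params()), 1764L)  # 7*7*4*9
  set.seed(12)
  for (rep in 1:5) {
    cell <- sample(c(4L, 8L, 16L), 1)
    ncell <- sample(4:8, 1)
    block <- sample(2:3, 1)
    overlap <- sample(0:(block - 1L), 1)
    p <- hog_params(window = cell * ncell, cell = cell, block = block,
                    overlap = overlap, n_bins = sample(6:12, 1))
    expect_identical(hog_length(p), brute_force_hog_length(p))
    img <- matrix(runif(p$window^2), p$window)
    expect_length(hog_descriptor(img, p), hog_length(p))
  }
  expect_error(hog_params(window = 60, cell = 8), "divisible")
})

test_that("constant images give an all-zero HOG descriptor", {
  img <- matrix(0.4, 64, 64)
  expect_true(all(hog_descriptor(img) == 0))
})

test_that("a step edge concentrates histogram mass in its orientation bin", {
  # horizontal edge: gradient along y, orientation 90 deg = center of bin 5
  img <- matrix(0, 64, 64)
  img[33:64, ] <- 1
  v <- hog_descriptor(img)
  byb <- matrix(v, nrow = 9)  # every 9 consecutive values are one cell histogram
  mass <- rowSums(byb)
  expect_gt(mass[5] / sum(mass), 1 - 1e-10)
})

test_that("HOG is non-negative, block-normalized, and intensity-scale invariant", {
  ds <- fixture_dataset(10)
  img <- ds$samples[[4]]$image
  p <- hog_params()
  v <- hog_descriptor(img, p)
  expect_true(all(v >= 0))
  blocks <- matrix(v, nrow = p$block^2 * p$n_bins)
  expect_true(all(colSums(blocks^2) <= 1 + 1e-9))
  v2 <- hog_descriptor(img * 0.37, p)
  expect_lt(max(abs(v - v2)), 1e-6)
})
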
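test_that("one gentleboost iteration solves 1-D separable data and matches exhaustive stump search", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- gentleboost(x, y, n_iter = 1)
  pr <- predict(m, x)
  expect_equal(pr$label, y)

  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30)
  y2 <- ifelse(X[, 3] + 0.2 * rnorm(30) > 0, 1, -1)
  m2 <- gentleboost(X, y2, n_iter = 1)
  oracle <- brute_force_stump(X, y2)
  expect_identical(m2$stumps$feature[1], oracle$feature)
  expect_equal(m2$stumps$threshold[1], oracle$threshold)
  expect_equal(m2$stumps$left[1], oracle$left)
  expect_equal(m2$stumps$right[1], oracle$right)
})

test_that("no single stump exceeds 3/4 accuracy on XOR", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  X <- X[rep(1:4, each = 5), ] + matrix(rnorm(40, sd = 0.01), 20)
  y <- ifelse(xor(X[, 1] > 0.5, X[, 2] > 0.5), 1, -1)
  m <- gentleboost(X, y, n_iter = 1)
  expect_lte(mean(predict(m, X)$label == y), 0.75)
})

test_that("gentleboost exponential loss is non-increasing over iterations", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40)
  y <- ifelse(X[, 1] - X[, 2] + rnorm(40, sd = 0.5) > 0, 1, -1)
  m <- gentleboost(X, y, n_iter = 30)
  expect_true(all(diff(m$loss) <= 1e-10))
  expect_error(gentleboost(X, rep(1, 40), 5), "single-class")
})

test_that("kNN matches a brute-force all-pairs distance scan", {
  set.seed(17)
  Xtr <- matrix(rnorm(50 * 20), 50)
  ytr <- sample(c(-1, 1), 50, replace = TRUE)
  Xte <- matrix(rnorm(20 * 20), 20)
  m <- facetraits:::knn_fit(Xtr, ytr, k = 5)
  got <- predict(m, Xte)
  want <- brute_force_knn(Xtr, ytr, Xte, 5)
  expect_equal(got$label, unname(want[, "label"]))
  expect_equal(got$confidence, unname(want[, "confidence"]))

  # cross-check against the class package's kNN (majority labels)
  skip_if_not_installed("class")
  cl <- class::knn(Xtr, Xte, factor(ytr), k = 5)
  expect_equal(got$label, as.numeric(as.character(cl)))
})

test_that("kNN majority vote yields the vote share as confidence", {
  Xtr <- matrix(c(0, 0.1, 0.2, 0.3, 10), ncol = 1)
  ytr <- c(1, 1, 1, -1, -1)
  m <- facetraits:::knn_fit(Xtr, ytr, k = 5)
  pr <- predict(m, matrix(0.15, 1, 1))
  expect_equal(pr$label, 1)
  expect_equal(pr$confidence, 0.6)

  Xtr2 <- matrix(c(0, 0.1, 0.2, 0.3, 0.4, 10), ncol = 1)
  ytr2 <- c(1, 1, 1, 1, -1, -1)
  m2 <- facetraits:::knn_fit(Xtr2, ytr2, k = 5)
  pr2 <- predict(m2, matrix(0.2, 1, 1))  # 4 of 5 neighbours are class
  expect_equal(pr2$confidence, 0.8)
})

test_that("parzen ensemble with M=1, rho=1 equals the plain Parzen classifier", {
  set.seed(23)
  Xtr <- matrix(rnorm(40 * 6), 40)
  ytr <- rep(c(-1, 1), 20)
  Xte <- matrix(rnorm(15 * 6), 15)
  set.seed(1)
  m <- facetraits:::parzen_rs_fit(Xtr, ytr, M = 1, rho = 1)
  got <- predict(m, Xte)
  # independent plain-Parzen oracle: two-class Gaussian product-kernel KDE
  bw_of <- function(x) {
    n <- length(x); s <- sd(x); iqr <- IQR(x) / 1.34
    max(0.9 * min(s, ifelse(iqr > 0, iqr, s)) * n^(-1 / 5), 1e-3)
  }
  dens <- function(tr, z) {
    bw <- apply(tr, 2, bw_of)
    mean(exp(-0.5 * colSums(((t(tr) - z) / bw)^2))) / prod(bw)
  }
  want <- apply(Xte, 1, function(z) {
    if (dens(Xtr[ytr == 1, ], z) >= dens(Xtr[ytr == -1, ], z)) 1 else -1
  })
  expect_equal(got$label, want)
  expect_true(all(got$confidence == 1))  # single member: unanimous vote
})

test_that("every bank classifier is symmetric under label swap", {
  set.seed(29)
  n <- 40
  X <- matrix(rnorm(n * 10), n)
  y <- ifelse(X[, 1] + 0.8 * rnorm(n) > 0, 1, -1)
  Xte <- matrix(rnorm(20 * 10), 20)
  yte <- ifelse(Xte[, 1] + 0.8 * rnorm(20) > 0, 1, -1)
  for (method in c("gentleboost", "svm_rbf", "tree", "knn", "parzen_rs")) {
    spec <- classifier_spec(method)
    set.seed(77)
    a <- classifier_bank(spec, list(x = X, y = y), Xte)
    set.seed(77)
    b <- classifier_bank(spec, list(x = X, y = -y), Xte)
    expect_equal(mean(a$label == yte), mean(b$label == -yte),
                 info = method)
  }
})

test_that("classifier specs validate their hyperparameters", {
  expect_error(classifier_spec("knn", k = 4), "odd")
  expect_error(classifier_spec("gentleboost", n_iter = 0), ">= 1")
  expect_error(classifier_spec("parzen_rs", rho = 1.5), "rho")
  expect_error(classifier_spec("lda"), "arg")

  # dimension mismatch at prediction time is caught
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rep(c(-1, 1), 15)
  fit <- fit_classifier(classifier_spec("knn"), X, y)
  expect_error(predict(fit, matrix(0, 2, 4)), "dimension")
})
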
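test_that("predicted-label correlation is the phi coefficient with defined edge cases", {
  a <- c(1, 1, -1, -1, 1, -1)
  expect_equal(as.numeric(prediction_label_correlation(a, a)), 1)
  expect_equal(as.numeric(prediction_label_correlation(a, -a)), -1)

  # balanced vectors agreeing on exactly half the samples: phi = 0
  b <- c(1, -1, -1, 1, 1, -1)  # agrees with a on positions 1,3,5 only? check
  a4 <- c(1, 1, -1, -1)
  b4 <- c(1, -1, 1, -1)
  expect_equal(as.numeric(prediction_label_correlation(a4, b4)), 0)

  const <- rep(1, 6)
  r <- prediction_label_correlation(a, const)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))

  # symmetry and invariance to consistent relabeling of both vectors
  set.seed(2)
  x <- sign(rnorm(30)); y <- sign(rnorm(30))
  expect_equal(prediction_label_correlation(x, y),
               prediction_label_correlation(y, x))
  expect_equal(prediction_label_correlation(-x, -y),
               prediction_label_correlation(x, y))

  expect_error(prediction_label_correlation(x, y[-1]), "aligned")
  expect_error(prediction_label_correlation(setNames(a4, letters[1:4]),
                                            setNames(b4, letters[4:1])),
               "misaligned")
})

test_that("feature-trait correlation handles perfect and constant columns", {
  y <- rep(c(1, -1), 10)
  X <- cbind(equal = y, const = rep(3, 20), noise = rnorm(20))
  r <- feature_trait_correlation(X, y)
  expect_equal(unname(r["equal"]), 1)
  expect_equal(unname(r["const"]), 0)
  expect_true(attr(r, "flagged")["const"])
  expect_false(attr(r, "flagged")["equal"])
  expect_error(feature_trait_correlation(X[1:5, ], y), "mismatch")
})

test_that("point importance counts landmark participation of selected features", {
  ft <- descriptor_feature_table(21)
  co <- numeric(nrow(ft))
  co[ft$name == "s3_d_05_09"] <- 0.9
  co[ft$name == "s3_d_02_05"] <- 0.8
  imp <- point_importance(co, ft, threshold = 0.5, type = "absolute")
  expect_equal(imp$counts[5], 2L)
  expect_equal(imp$counts[9], 1L)
  expect_equal(imp$counts[2], 1L)
  expect_equal(imp$normalized[5], 1)
  expect_equal(imp$normalized[9], 0.5)
  expect_true(all(imp$counts[-c(2, 5, 9)] == 0))

  # select-all: counts equal each point's total multiplicity in the feature map
  imp_all <- point_importance(runif(nrow(ft)), ft, threshold = 0, type = "quantile")
  tally <- integer(21)
  for (r in seq_len(nrow(ft))) {
    tally[ft$i[r]] <- tally[ft$i[r]] + 1L
    if (!is.na(ft$j[r])) tally[ft$j[r]] <- tally[ft$j[r]] + 1L
  }
  expect_identical(imp_all$counts, tally)

  expect_warning(point_importance(co, ft, threshold = 2, type = "absolute"),
                 "no feature")
})

test_that("angle/distance share reflects the selection and the full partition", {
  ft <- descriptor_feature_table(21)
  co <- numeric(nrow(ft))
  co[ft$set == 3][1:5] <- 1
  sh <- angle_vs_distance_share(co, ft, threshold = 0.5, type = "absolute")
  expect_equal(unname(sh$share["distance"]), 1)
  expect_equal(unname(sh$counts["angle"]), 0L)

  sh_all <- angle_vs_distance_share(rep(1, nrow(ft)), ft, threshold = 0,
                                    type = "quantile")
  expect_identical(sh_all$counts,
                   c(radius = 462L, angle = 462L, distance = 210L))
})

test_that("planted mouth signal surfaces in feature correlation and importance", {
  ds <- fixture_dataset(120, seed = 55)
  ids <- fixture_ids(ds)
  scm <- fixture_scores(ds)
  bl <- binarize_scores(setNames(scm[, "extroverted"], ids))
  gm <- geometric_descriptor_matrix(fixture_landmarks(ds))
  sel <- match(bl$ids, ids)
  co <- feature_trait_correlation(gm$features[sel, ], bl$labels)
  ft <- gm$feature_table
  # the mouth-corner distance feature ranks among the top |correlation|
  # features; the few features above it are themselves mouth-corner
  # relations (deterministic functions of the same planted mode, so their
  # correlations tie within sampling noise)
  ord <- order(-abs(co))
  rank_of <- which(ft$name[ord] == "s3_d_13_15")
  expect_lte(rank_of, ceiling(0.05 * nrow(ft)))
  above <- ord[seq_len(rank_of - 1)]
  touches_mouth <- ft$i[above] %in% c(13L, 15L) | ft$j[above] %in% c(13L, 15L)
  expect_true(all(touches_mouth))
  # mouth-corner landmarks attain the top-2 normalized counts
  imp <- point_importance(co, ft, threshold = 0.95)
  top2 <- order(imp$normalized, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(13, 15))
})

test_that("trait PCA recovers planted low-rank structure", {
  set.seed(7)
  # two perfectly correlated traits, third constant (flagged + dropped)
  X <- cbind(a = rnorm(50))
  X <- cbind(X, b = 2 * X[, 1] + 3, c = rep(1, 50))
  p <- trait_pca_projection(X)
  expect_equal(p$variance_shares[1], 1)
  expect_identical(p$dropped, "c")
  expect_equal(sum(p$variance_shares), 1)

  # nine traits from two independent latent factors: two PCs carry ~all variance
  u <- rnorm(200); v <- rnorm(200)
  L <- sapply(1:9, function(i) {
    if (i <= 5) u * (0.5 + 0.1 * i) + v * 0.05 else v * (0.4 + 0.1 * i) + u * 0.05
  })
  L <- L + matrix(rnorm(200 * 9, sd = 0.05), 200)
  p2 <- trait_pca_projection(L)
  expect_gte(sum(p2$variance_shares[1:2]), 0.95)
  expect_identical(dim(p2$projections), c(200L, 2L))
  expect_error(trait_pca_projection(L[1:2, ]), "at least 3")
})

test_that("confidence ranking orders a gallery by planted signal strength", {
  ds <- fixture_dataset(120, seed = 55)
  ids <- fixture_ids(ds)
  scm <- fixture_scores(ds)
  bl <- binarize_scores(setNames(scm[, "extroverted"], ids))
  gm <- geometric_descriptor_matrix(fixture_landmarks(ds))
  sel <- match(bl$ids, ids)
  fit <- fit_classifier(classifier_spec("gentleboost"),
                        gm$features[sel, ], bl$labels)

  # gallery with graded mouth widths
  sm <- ds$shape_model
  cfg <- ds$config
  widths <- seq(-3, 3, length.out = 13)
  gal_lms <- lapply(widths, function(d) {
    lm <- sm$mean_shape
    lm["mouth_l", "x"] <- lm["mouth_l", "x"] - d
    lm["mouth_r", "x"] <- lm["mouth_r", "x"] + d
    lm
  })
  G <- t(vapply(gal_lms, function(lm)
    as.numeric(geometric_descriptor(lm, gm$mean_shape, gm$feature_table)),
    numeric(1134)))
  rownames(G) <- sprintf("g%02d", seq_along(widths))
  rk <- rank_by_confidence(fit, G)
  pos <- match(rownames(G), rk$id)  # rank position of each gallery face
  expect_gte(abs(cor(pos, widths, method = "spearman")), 0.8)

  # basic ordering contract
  expect_true(all(diff(rk$score) <= 0))
  expect_error(rank_by_confidence(list(), G), "trait_clf")
})
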
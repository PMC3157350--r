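test_that("shape model: orthonormal modes, determinism, degenerate cases", {
  sm <- build_shape_model(shape_modes = 8, seed = 7)
  G <- crossprod(sm$modes)
  expect_lt(max(abs(G - diag(8))), 1e-10)
  sm2 <- build_shape_model(shape_modes = 8, seed = 7)
  expect_identical(sm$modes, sm2$modes)

  sm0 <- build_shape_model(shape_modes = 0)
  cfg <- synthetic_config(n_faces = 1, shape_modes = 0, seed = 1)
  s <- facetraits::sample_face(sm0, cfg, "a")
  expect_equal(s$landmarks, sm0$mean_shape)

  expect_error(build_shape_model(shape_modes = 43), "invalid config")
})

test_that("rendering is a deterministic function of landmarks", {
  sm <- build_shape_model()
  cfg <- synthetic_config(n_faces = 1, seed = 2)
  s1 <- sample_face(sm, cfg, "a", coefficients = rep(0, 5))
  img_mean <- render_face(sm$mean_shape, 64, s1$skin_tone, s1$brow_shade)
  expect_equal(s1$image, img_mean)
})

test_that("widening the mouth corners widens the rendered mouth accordingly", {
  tmpl <- face_template()
  wide <- tmpl
  wide["mouth_l", "x"] <- wide["mouth_l", "x"] - 4
  wide["mouth_r", "x"] <- wide["mouth_r", "x"] + 4
  measure <- function(img, y_row) {
    dark <- which(img[y_row + 1, 17:48] < 0.52)  # lip is darker than skin
    diff(range(dark))
  }
  y <- round(tmpl["mouth_l", "y"])
  w0 <- measure(render_face(tmpl), y)
  w1 <- measure(render_face(wide), y)
  expect_equal(w1 - w0, 8, tolerance = 2 / 8)  # rasterization/blur: ±2 px
})

test_that("sampled landmark spread matches the model's analytic covariance", {
  sm <- build_shape_model()
  cfg <- synthetic_config(n_faces = 100, mode_sd = 2, seed = 33)
  set.seed(33)
  lms <- replicate(100, sample_face(sm, cfg, "x")$landmarks,
                   simplify = FALSE)
  coords <- t(vapply(lms, function(lm) as.vector(lm), numeric(42)))
  emp_sd <- apply(coords, 2, sd)
  # marginal sd of coordinate c = mode_sd * ||row c of mode matrix||
  ana_sd <- cfg$mode_sd * sqrt(rowSums(sm$modes^2))
  moving <- ana_sd > 0.1
  expect_true(all(abs(emp_sd[moving] - ana_sd[moving]) / ana_sd[moving] < 0.25))
})

test_that("trait scores follow the planted linear model", {
  sm <- build_shape_model()
  cfg <- synthetic_config(n_faces = 1, seed = 3)
  set.seed(3)
  s <- sample_face(sm, cfg, "a")
  # monotone map: extroversion weight on mouth width, no noise
  spec <- list(trait_spec("extroverted", c(mouth_width = 1), intercept = 0,
                          noise_sd = 0))
  set.seed(9)
  widths <- c(10, 14, 18)
  scores <- vapply(widths, function(w) {
    lm <- sm$mean_shape
    lm["mouth_l", "x"] <- lm["mouth_top", "x"] - w / 2
    lm["mouth_r", "x"] <- lm["mouth_top", "x"] + w / 2
    s2 <- s; s2$landmarks <- lm
    assign_trait_scores(s2, spec)$scores[["extroverted"]]
  }, numeric(1))
  expect_identical(order(scores), order(widths))

  # unknown feature names are rejected with the known list
  bad <- list(trait_spec("dominant", c(nose_length = 1)))
  expect_error(assign_trait_scores(s, bad), "unknown feature.*mouth_width")

  # zero-weight specs are invalid (planted signal required)
  expect_error(trait_spec("dominant", c(mouth_width = 0)), "nonzero")
})

test_that("noise calibrated for R^2 = 0.8 yields corr(score, feature) near sqrt(0.8)", {
  # mouth-width marginal sd is mode_sd * sqrt(2) under the mouth-width mode
  w <- 0.5; mode_sd <- 2
  planted_sd <- w * mode_sd * sqrt(2)
  noise_sd <- planted_sd * sqrt(1 / 0.8 - 1)
  ref <- face_features(face_template())
  spec <- list(trait_spec("extroverted", c(mouth_width = w),
                          intercept = 5 - w * ref[["mouth_width"]],
                          noise_sd = noise_sd))
  cfg <- synthetic_config(n_faces = 300, trait_specs = spec, seed = 41)
  ds <- generate_dataset(cfg)
  sc <- vapply(ds$samples, function(s) s$scores[["extroverted"]], numeric(1))
  mw <- vapply(ds$samples, function(s)
    face_features(s)[["mouth_width"]], numeric(1))
  expect_gt(cor(sc, mw), 0.85)
  expect_lt(cor(sc, mw), 0.93)
})

test_that("dataset generation is deterministic and writes the documented layout", {
  cfg <- synthetic_config(n_faces = 10, seed = 7)
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_dataset(cfg, out_dir = d1, overwrite = TRUE)
  generate_dataset(cfg, out_dir = d2, overwrite = TRUE)
  expect_identical(readBin(file.path(d1, "scores.csv"), "raw", 1e6),
                   readBin(file.path(d2, "scores.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "landmarks.csv"), "raw", 1e6),
                   readBin(file.path(d2, "landmarks.csv"), "raw", 1e6))

  lm <- read.csv(file.path(d1, "landmarks.csv"))
  expect_identical(dim(lm), c(10L, 1L + 2L * 21L))
  sc <- read.csv(file.path(d1, "scores.csv"))
  expect_true(all(trait_names() %in% names(sc)))

  # refuses to clobber an existing directory
  expect_error(generate_dataset(cfg, out_dir = d1), "overwrite")
})

test_that("datasets round-trip through disk", {
  cfg <- synthetic_config(n_faces = 6, seed = 13)
  dir <- file.path(tempdir(), "ds_rt")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ds <- generate_dataset(cfg, out_dir = dir, overwrite = TRUE)
  back <- read_dataset(dir)
  expect_length(back, 6)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$id, ds$samples[[i]]$id)
    expect_equal(back[[i]]$landmarks, ds$samples[[i]]$landmarks,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back[[i]]$scores, ds$samples[[i]]$scores, tolerance = 1e-6)
    expect_equal(back[[i]]$image, ds$samples[[i]]$image, tolerance = 1e-9)
  }
})

test_that("dataset reader validates ids, traits and landmark counts", {
  cfg <- synthetic_config(n_faces = 4, seed = 19)
  dir <- file.path(tempdir(), "ds_bad")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  generate_dataset(cfg, out_dir = dir, overwrite = TRUE)

  sc <- read.csv(file.path(dir, "scores.csv"))
  write.csv(sc[, setdiff(names(sc), "dominant")],
            file.path(dir, "scores.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "dominant")

  generate_dataset(cfg, out_dir = dir, overwrite = TRUE)
  expect_error(read_dataset(dir, n_points = 20), "expected")

  sc <- read.csv(file.path(dir, "scores.csv"))
  sc$id[1] <- "rogue"
  write.csv(sc, file.path(dir, "scores.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "mismatch")
})

test_that("out-of-bounds landmark samples error after the retry cap", {
  sm <- build_shape_model()
  cfg <- synthetic_config(n_faces = 1, mode_sd = 200, seed = 1)
  set.seed(1)
  expect_error(sample_face(sm, cfg, "a"), "outside the image")
})
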
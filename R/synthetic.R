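# Synthetic face generator: a linear statistical shape model around the
# 21-point template, a deterministic landmark-driven renderer, and trait
# scores planted on named structural/appearance features.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Linear shape model around the landmark template
#'
#' Builds a mean shape (the fixed anatomical template scaled into image
#' coordinates) and an orthonormal basis of landmark-deformation modes.
#' The leading modes are structured, interpretable directions (eye spacing,
#' mouth width, chin drop, face width, brow raise); further modes, if
#' requested, are seeded random directions orthonormalized against them.
#' Mode vectors live in R^(2P), layout `c(x_1..x_P, y_1..y_P)`.
#'
#' @param n_points Landmark count; must match the 21-point template.
#' @param shape_modes Number of deformation modes (0 allowed; at most 2P).
#' @param seed Integer seed for the random filler modes.
#' @param size Image side length in pixels.
#' @return List with `mean_shape` (P x 2), `modes` (2P x shape_modes,
#'   orthonormal columns), `size`.
#' @export
build_shape_model <- function(n_points = 21L, shape_modes = 5L, seed = 1L,
                              size = 64L) {
  if (n_points != 21L)
    stop("invalid config: n_points must be 21 (the fiducial template layout)")
  if (shape_modes > 2L * n_points)
    stop("invalid config: shape_modes may not exceed 2 * n_points = ",
         2L * n_points)
  if (shape_modes < 0L) stop("invalid config: shape_modes must be >= 0")
  mean_shape <- face_template(size)
  P <- n_points
  idx <- function(nm) match(nm, rownames(mean_shape))
  dir <- function(xs = NULL, ys = NULL) {
    v <- numeric(2L * P)
    if (!is.null(xs)) for (nm in names(xs)) v[idx(nm)] <- xs[[nm]]
    if (!is.null(ys)) for (nm in names(ys)) v[P + idx(nm)] <- ys[[nm]]
    v / sqrt(sum(v^2))
  }
  semantic <- cbind(
    # eye spacing: brow+eye clusters move apart
    dir(xs = c(brow_l_out = -1, brow_l_in = -1, eye_l_out = -1, eye_l_in = -1,
               brow_r_out = 1, brow_r_in = 1, eye_r_out = 1, eye_r_in = 1)),
    # mouth width
    dir(xs = c(mouth_l = -1, mouth_r = 1)),
    # chin drop (lengthens lower face)
    dir(ys = c(chin = 1, jaw_l = 0.6, jaw_r = 0.6, mouth_bottom = 0.3)),
    # face width
    dir(xs = c(cheek_l = -1, cheek_r = 1, jaw_l = -0.6, jaw_r = 0.6)),
    # brow raise
    dir(ys = c(brow_l_out = -1, brow_l_in = -1, brow_r_in = -1, brow_r_out = -1))
  )
  if (shape_modes == 0L) {
    modes <- matrix(0, 2L * P, 0L)
  } else if (shape_modes <= ncol(semantic)) {
    modes <- semantic[, seq_len(shape_modes), drop = FALSE]
  } else {
    extra <- with_seed(seed, matrix(stats::rnorm(2L * P * (shape_modes - ncol(semantic))),
                                    nrow = 2L * P))
    modes <- cbind(semantic, extra)
  }
  if (ncol(modes) > 0L) {
    qr_ <- qr(modes)
    modes <- qr.Q(qr_)[, seq_len(ncol(modes)), drop = FALSE]
    # deterministic sign convention: largest-|.| entry positive
    for (k in seq_len(ncol(modes))) {
      top <- which.max(abs(modes[, k]))
      if (modes[top, k] < 0) modes[, k] <- -modes[, k]
    }
  }
  list(mean_shape = mean_shape, modes = modes, size = as.integer(size))
}

#' Synthetic dataset configuration
#'
#' @param n_faces Number of faces to generate.
#' @param n_points Landmarks per face (21).
#' @param shape_modes Deformation modes of the shape model.
#' @param mode_sd Per-mode coefficient standard deviation, pixels.
#' @param image_size `c(height, width)` in pixels (square).
#' @param trait_specs List of [trait_spec()] objects (defaults to
#'   [default_trait_specs()]).
#' @param rater_noise_sd Additive rating noise, 1--9 scale units, used by
#'   [default_trait_specs()] when `trait_specs` is not supplied.
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_faces = 300L, n_points = 21L, shape_modes = 5L,
                             mode_sd = 2, image_size = c(64L, 64L),
                             trait_specs = NULL, rater_noise_sd = 0.6,
                             seed = 1L) {
  if (n_points < 3L) stop("invalid config: n_points must be >= 3")
  if (mode_sd <= 0) stop("invalid config: mode_sd must be > 0")
  if (any(image_size <= 0)) stop("invalid config: image dimensions must be positive")
  if (image_size[1L] != image_size[2L]) stop("invalid config: square images only")
  if (is.null(trait_specs)) trait_specs <- default_trait_specs(rater_noise_sd)
  structure(list(n_faces = as.integer(n_faces), n_points = as.integer(n_points),
                 shape_modes = as.integer(shape_modes), mode_sd = mode_sd,
                 image_size = as.integer(image_size), trait_specs = trait_specs,
                 rater_noise_sd = rater_noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Planted trait-score specification
#'
#' A trait score is `clip(intercept + sum(w * feature) + N(0, noise_sd), 1, 9)`
#' where features are named structural measurements (e.g. `mouth_width`,
#' `interocular`, `brow_height`) or appearance statistics (`skin_tone`,
#' `brow_shade`, `mouth_region_intensity`) of the generated face.
#'
#' @param trait_name One of [trait_names()].
#' @param weights Named numeric vector of feature coefficients; at least one
#'   must be nonzero.
#' @param intercept Baseline rating.
#' @param noise_sd Rater-like additive Gaussian noise, rating units.
#' @return A `trait_spec` object.
#' @export
trait_spec <- function(trait_name, weights, intercept = 5, noise_sd = 0.6) {
  if (!trait_name %in% trait_names())
    stop("unknown trait: ", trait_name)
  if (length(weights) == 0L || all(weights == 0) || is.null(names(weights)))
    stop("trait_spec needs at least one nonzero named weight")
  structure(list(trait_name = trait_name, weights = weights,
                 intercept = intercept, noise_sd = noise_sd),
            class = "trait_spec")
}

#' Default planted specifications for the nine traits
#'
#' Traits share features so that inter-trait correlations arise: a
#' dominance-like group (dominant, threatening, mean, frightening) loads on
#' lowered brows, face width and brow shade; a valence-like group
#' (attractive, trustworthy, likable, extroverted, competent) loads on eye
#' spacing, mouth width and skin tone.  `likable` is planted on appearance
#' only (skin tone), so structural classifiers cannot learn it — a contrast
#' used when comparing descriptor channels.
#'
#' Intercepts are set so a template-average face scores 5 on every trait.
#'
#' @param noise_sd Rating noise common to all traits.
#' @return Named list of nine [trait_spec()] objects.
#' @export
default_trait_specs <- function(noise_sd = 0.6) {
  ref <- c(face_features(face_template(64)),
           skin_tone = 0.72, brow_shade = 0.25, mouth_region_intensity = 0.35)
  mk <- function(trait, w) {
    trait_spec(trait, w, intercept = 5 - sum(w * ref[names(w)]),
               noise_sd = noise_sd)
  }
  sp <- list(
    mk("attractive",  c(interocular = 0.5, skin_tone = 8)),
    mk("competent",   c(interocular = 0.35, brow_shade = 6)),
    mk("trustworthy", c(mouth_width = 0.25, brow_height = 0.7)),
    mk("dominant",    c(brow_height = -0.9, face_width = 0.25, brow_shade = 8)),
    mk("mean",        c(brow_height = -0.8, mouth_width = -0.2)),
    mk("frightening", c(brow_height = -0.7, brow_shade = 7, skin_tone = -6)),
    mk("extroverted", c(mouth_width = 0.45)),
    mk("threatening", c(brow_height = -0.8, face_width = 0.3, brow_shade = 6)),
    mk("likable",     c(skin_tone = 20))
  )
  names(sp) <- vapply(sp, `[[`, "", "trait_name")
  sp
}

#' Structural and appearance features of a face sample
#'
#' The named measurements available to [trait_spec()] weights.
#'
#' @param sample A `face_sample` (or a bare landmark matrix, in which case
#'   appearance features are omitted).
#' @return Named numeric vector.
#' @export
face_features <- function(sample) {
  lm <- if (is.matrix(sample)) sample else sample$landmarks
  g <- function(nm) lm[landmark_index(nm, lm), ]
  d <- function(a, b) sqrt(sum((g(a) - g(b))^2))
  eye_l <- (g("eye_l_out") + g("eye_l_in")) / 2
  eye_r <- (g("eye_r_out") + g("eye_r_in")) / 2
  f <- c(
    interocular = sqrt(sum((eye_l - eye_r)^2)),
    mouth_width = d("mouth_l", "mouth_r"),
    chin_mouth  = d("chin", "mouth_bottom"),
    face_width  = d("cheek_l", "cheek_r"),
    jaw_width   = d("jaw_l", "jaw_r"),
    nose_width  = d("nose_l", "nose_r"),
    brow_height = mean(c(g("eye_l_out")[2], g("eye_l_in")[2], g("eye_r_in")[2],
                         g("eye_r_out")[2])) -
                  mean(c(g("brow_l_out")[2], g("brow_l_in")[2],
                         g("brow_r_in")[2], g("brow_r_out")[2])),
    eye_width   = (d("eye_l_out", "eye_l_in") + d("eye_r_out", "eye_r_in")) / 2
  )
  if (!is.matrix(sample)) {
    img <- sample$image
    ml <- g("mouth_l"); mr <- g("mouth_r"); mt <- g("mouth_top"); mb <- g("mouth_bottom")
    rows <- seq(max(1, floor(mt[2])), min(nrow(img), ceiling(mb[2]) + 1))
    cols <- seq(max(1, floor(ml[1])), min(ncol(img), ceiling(mr[1]) + 1))
    f <- c(f,
           skin_tone = sample$skin_tone,
           brow_shade = sample$brow_shade,
           mouth_region_intensity = mean(img[rows, cols]))
  }
  f
}

#' Sample one face from a shape model
#'
#' Landmark perturbation is `modes %*% coefficients` with coefficients drawn
#' `N(0, mode_sd^2)` from the current RNG stream; appearance latents (skin
#' tone, brow shade) are drawn likewise; the image is then a deterministic
#' rendering of landmarks and latents.  Samples with any landmark outside the
#' image are redrawn up to 10 times.
#'
#' @param shape_model From [build_shape_model()].
#' @param config A [synthetic_config()].
#' @param id Sample identifier string.
#' @param coefficients Optional fixed mode coefficients (bypasses sampling).
#' @return A `face_sample`: list with `id`, `image`, `landmarks`,
#'   `skin_tone`, `brow_shade`, `scores` (NULL until assigned).
#' @export
sample_face <- function(shape_model, config, id = "face", coefficients = NULL) {
  P <- nrow(shape_model$mean_shape)
  size <- config$image_size[1L]
  for (try in seq_len(10L)) {
    cf <- if (is.null(coefficients)) stats::rnorm(ncol(shape_model$modes), 0, config$mode_sd)
          else coefficients
    delta <- if (length(cf)) shape_model$modes %*% cf else numeric(2L * P)
    lm <- shape_model$mean_shape + matrix(delta, P, 2L)
    skin <- min(max(stats::rnorm(1, 0.72, 0.05), 0.5), 0.9)
    brow <- min(max(stats::rnorm(1, 0.25, 0.06), 0.05), 0.45)
    if (all(lm >= 1) && all(lm <= size - 2)) {
      img <- render_face(lm, size, skin_tone = skin, brow_shade = brow)
      return(structure(list(id = id, image = img, landmarks = lm,
                            skin_tone = skin, brow_shade = brow, scores = NULL),
                       class = "face_sample"))
    }
    if (!is.null(coefficients)) break
  }
  stop("sampled landmarks fell outside the image in 10 attempts; ",
       "reduce mode_sd or enlarge the image")
}

#' Assign planted trait scores to a face sample
#'
#' @param sample A `face_sample`.
#' @param trait_specs List of [trait_spec()] objects.
#' @return The sample with `$scores` set (named numeric, clipped to [1, 9]).
#' @export
assign_trait_scores <- function(sample, trait_specs) {
  feats <- face_features(sample)
  lo <- rating_range()[1L]; hi <- rating_range()[2L]
  scores <- vapply(trait_specs, function(sp) {
    unknown <- setdiff(names(sp$weights), names(feats))
    if (length(unknown))
      stop("unknown feature(s) ", paste(unknown, collapse = ", "),
           " in trait_spec '", sp$trait_name, "'; known features: ",
           paste(names(feats), collapse = ", "))
    raw <- sp$intercept + sum(sp$weights * feats[names(sp$weights)]) +
      stats::rnorm(1, 0, sp$noise_sd)
    min(max(raw, lo), hi)
  }, numeric(1))
  names(scores) <- vapply(trait_specs, `[[`, "", "trait_name")
  sample$scores <- scores
  sample
}

#' @export
print.face_sample <- function(x, ...) {
  cat("face_sample '", x$id, "': ", nrow(x$landmarks), " landmarks, ",
      nrow(x$image), "x", ncol(x$image), " image",
      if (!is.null(x$scores)) ", scored" else ", unscored", "\n", sep = "")
  invisible(x)
}
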
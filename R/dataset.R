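# Dataset generation and on-disk layout:
#   <dir>/images/<id>.png        8-bit grayscale
#   <dir>/landmarks.csv          id,x1,y1,...,x21,y21  (0-based pixels)
#   <dir>/scores.csv             id,attractive,...,likable
#   <dir>/manifest.yaml          config + seed (no timestamps: runs are
#                                reproducible byte for byte)

#' Generate a synthetic face dataset
#'
#' Draws `n_faces` faces from the shape model, renders them, assigns planted
#' trait scores, and (optionally) writes the dataset to disk.  A fixed seed
#' yields a byte-identical dataset.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory; refused if it exists unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing directory.
#' @return List with `samples` (list of `face_sample`), `shape_model`,
#'   `config`, and `manifest`.
#' @export
generate_dataset <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  shape_model <- build_shape_model(config$n_points, config$shape_modes,
                                   seed = config$seed,
                                   size = config$image_size[1L])
  wd <- max(3L, nchar(as.character(config$n_faces)))
  samples <- with_seed(config$seed, {
    lapply(seq_len(config$n_faces), function(i) {
      s <- sample_face(shape_model, config,
                       id = sprintf(paste0("face%0", wd, "d"), i))
      assign_trait_scores(s, config$trait_specs)
    })
  })
  manifest <- list(
    generator = "facetraits synthetic_faces",
    seed = config$seed, n_faces = config$n_faces,
    n_points = config$n_points, shape_modes = config$shape_modes,
    mode_sd = config$mode_sd, image_size = as.integer(config$image_size),
    rater_noise_sd = config$rater_noise_sd,
    traits = lapply(config$trait_specs, function(sp)
      list(trait = sp$trait_name, weights = as.list(sp$weights),
           intercept = sp$intercept, noise_sd = sp$noise_sd))
  )
  out <- list(samples = samples, shape_model = shape_model, config = config,
              manifest = manifest)
  if (!is.null(out_dir)) write_dataset(out, out_dir, overwrite = overwrite)
  out
}

landmark_header <- function(P) {
  c("id", as.vector(rbind(paste0("x", seq_len(P)), paste0("y", seq_len(P)))))
}

#' Write a generated dataset to disk
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite)
    stop("output directory '", dir, "' exists; pass overwrite = TRUE")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  samples <- dataset$samples
  P <- nrow(samples[[1L]]$landmarks)
  ids <- vapply(samples, `[[`, "", "id")
  lm <- t(vapply(samples, function(s) as.vector(t(s$landmarks)), numeric(2L * P)))
  lm_df <- data.frame(id = ids, round(lm, 6))
  names(lm_df) <- landmark_header(P)
  utils::write.csv(lm_df, file.path(dir, "landmarks.csv"), row.names = FALSE,
                   quote = FALSE)
  sc <- t(vapply(samples, function(s) s$scores[trait_names()],
                 numeric(length(trait_names()))))
  sc_df <- data.frame(id = ids, round(sc, 6))
  names(sc_df) <- c("id", trait_names())
  utils::write.csv(sc_df, file.path(dir, "scores.csv"), row.names = FALSE,
                   quote = FALSE)
  for (s in samples)
    png::writePNG(s$image, file.path(dir, "images", paste0(s$id, ".png")))
  yaml::write_yaml(dataset$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a face dataset from disk
#'
#' Loads images, landmarks and trait scores, validating that the three
#' sources agree on sample ids, that every face has the expected landmark
#' count, and that all nine trait columns are present.  Accommodates any
#' dataset following the layout written by [write_dataset()].
#'
#' @param dir Dataset directory.
#' @param n_points Expected landmark count.
#' @return List of `face_sample` objects (with `scores`; appearance latents
#'   are not recoverable from disk and are set to `NA`).
#' @export
read_dataset <- function(dir, n_points = 21L) {
  lm_path <- file.path(dir, "landmarks.csv")
  sc_path <- file.path(dir, "scores.csv")
  for (p in c(lm_path, sc_path))
    if (!file.exists(p)) stop("missing file: ", p)
  lm_df <- utils::read.csv(lm_path, check.names = FALSE)
  sc_df <- utils::read.csv(sc_path, check.names = FALSE)
  if (ncol(lm_df) != 1L + 2L * n_points)
    stop("landmark file has ", (ncol(lm_df) - 1L) / 2, " points; expected ",
         n_points)
  missing_tr <- setdiff(trait_names(), names(sc_df))
  if (length(missing_tr))
    stop("scores.csv is missing trait column(s): ",
         paste(missing_tr, collapse = ", "))
  img_files <- list.files(file.path(dir, "images"), pattern = "\\.png$")
  img_ids <- sub("\\.png$", "", img_files)
  miss_sc <- setdiff(lm_df$id, sc_df$id)
  miss_lm <- setdiff(sc_df$id, lm_df$id)
  miss_im <- setdiff(lm_df$id, img_ids)
  if (length(miss_sc) || length(miss_lm) || length(miss_im))
    stop("id mismatch across files; missing in scores.csv: ",
         paste(miss_sc, collapse = ","), "; missing in landmarks.csv: ",
         paste(miss_lm, collapse = ","), "; missing images: ",
         paste(miss_im, collapse = ","))
  tmpl_names <- rownames(face_template())
  lapply(seq_len(nrow(lm_df)), function(r) {
    id <- lm_df$id[r]
    lm <- matrix(as.numeric(lm_df[r, -1L]), ncol = 2L, byrow = TRUE)
    rownames(lm) <- if (n_points == 21L) tmpl_names else NULL
    colnames(lm) <- c("x", "y")
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    sc <- as.numeric(sc_df[match(id, sc_df$id), trait_names()])
    names(sc) <- trait_names()
    structure(list(id = id, image = img, landmarks = lm,
                   skin_tone = NA_real_, brow_shade = NA_real_, scores = sc),
              class = "face_sample")
  })
}
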
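# End-to-end experiment: data -> descriptors -> classifier-bank CV ->
# correlation / importance analyses, with a provenance manifest.

# deterministic sub-seed (< 2^31) for one cell of the experiment grid
subseed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "|")
  h <- sum(utf8ToInt(parts) * seq_along(utf8ToInt(parts)))
  as.integer((seed * 7919 + h) %% .Machine$integer.max)
}

#' Experiment configuration
#'
#' @param data A [synthetic_config()] (the dataset is generated) or a
#'   directory path (the dataset is read with [read_dataset()]).
#' @param descriptors Subset of `c("geometric", "eigenfaces", "hog")`.
#' @param classifiers Named list of [classifier_spec()]s (defaults to the
#'   full five-method bank).
#' @param traits Subset of [trait_names()].
#' @param n_folds,level CV folds and confidence level.
#' @param binarize_fraction Fraction per side for [binarize_scores()].
#' @param variance_fraction Eigenfaces retained variance.
#' @param hog HOG parameterization ([hog_params()]).
#' @param importance_threshold |correlation| quantile for feature selection.
#' @param correlation_classifier Bank member whose out-of-fold predictions
#'   feed the descriptor-pair label correlation (the paper's choice: SVM).
#' @param seed Master seed.
#' @return `experiment_config` list.
#' @export
experiment_config <- function(data = synthetic_config(),
                              descriptors = c("geometric", "eigenfaces", "hog"),
                              classifiers = default_classifier_bank(),
                              traits = trait_names(),
                              n_folds = 10L, level = 0.95,
                              binarize_fraction = 1 / 3,
                              variance_fraction = 0.95,
                              hog = hog_params(),
                              importance_threshold = 0.95,
                              correlation_classifier = "svm_rbf",
                              seed = 1L) {
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  stopifnot(all(traits %in% trait_names()))
  structure(list(data = data, descriptors = descriptors,
                 classifiers = classifiers, traits = traits,
                 n_folds = as.integer(n_folds), level = level,
                 binarize_fraction = binarize_fraction,
                 variance_fraction = variance_fraction, hog = hog,
                 importance_threshold = importance_threshold,
                 correlation_classifier = correlation_classifier,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' The default five-method classifier bank
#' @return Named list of [classifier_spec()]s.
#' @export
default_classifier_bank <- function() {
  list(gentleboost = classifier_spec("gentleboost"),
       svm_rbf = classifier_spec("svm_rbf"),
       tree = classifier_spec("tree"),
       knn = classifier_spec("knn"),
       parzen_rs = classifier_spec("parzen_rs"))
}

# featurizer factories: refit the fitted part of a descriptor on the
# training fold only
geometric_featurizer <- function(landmark_sets) {
  force(landmark_sets)
  function(train_idx, test_idx) {
    ms <- compute_mean_shape(landmark_sets[train_idx])
    ft <- descriptor_feature_table(nrow(ms))
    mk <- function(idx) t(vapply(landmark_sets[idx], function(lm)
      as.numeric(geometric_descriptor(lm, ms, ft)), numeric(nrow(ft))))
    list(train = mk(train_idx), test = mk(test_idx))
  }
}

eigen_featurizer <- function(images, variance_fraction) {
  force(images); force(variance_fraction)
  function(train_idx, test_idx) {
    mdl <- fit_eigenfaces(images[train_idx], variance_fraction)
    mk <- function(idx) t(vapply(images[idx], function(im)
      project_eigenfaces(mdl, im), numeric(mdl$k)))
    list(train = mk(train_idx), test = mk(test_idx))
  }
}

#' Run the full trait-prediction experiment
#'
#' Generates (or reads) the dataset, computes the selected descriptors
#' (shape-normalizing images for the holistic ones), evaluates every
#' classifier on every trait under stratified N-fold CV, and runs the
#' second-level analyses: predicted-label correlation between descriptor
#' pairs, geometric feature-trait correlation with landmark importance maps,
#' angle-vs-distance share, and the trait-space PCA.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory for CSV tables, importance PNGs
#'   and the manifest.
#' @param overwrite Allow writing into an existing directory.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `facetraits_experiment`.
#' @export
run_experiment <- function(config, out_dir = NULL, overwrite = FALSE,
                           verbose = TRUE) {
  say <- function(...) if (verbose) message("[facetraits] ", ...)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    say(nm, " ...")
    r <- tryCatch(expr, error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
    say(nm, sprintf(" done (%.1fs total)", proc.time()[["elapsed"]] - t0))
    r
  }

  samples <- stage("data", {
    if (inherits(config$data, "synthetic_config")) {
      generate_dataset(config$data)$samples
    } else read_dataset(config$data)
  })
  n <- length(samples)
  ids <- vapply(samples, `[[`, "", "id")
  landmark_sets <- lapply(samples, `[[`, "landmarks")
  score_mat <- t(vapply(samples, function(s) s$scores[config$traits],
                        numeric(length(config$traits))))
  rownames(score_mat) <- ids
  colnames(score_mat) <- config$traits

  feats <- stage("featurize", {
    out <- list()
    mean_shape <- compute_mean_shape(landmark_sets)
    out$mean_shape <- mean_shape
    if ("geometric" %in% config$descriptors)
      out$geometric <- geometric_featurizer(landmark_sets)
    if (any(c("eigenfaces", "hog") %in% config$descriptors)) {
      ref <- choose_reference(landmark_sets, mean_shape)
      warped <- lapply(samples, function(s)
        shape_normalize(s$image, s$landmarks, ref$shape))
      out$reference_index <- ref$index
      out$warped <- warped
      if ("hog" %in% config$descriptors) {
        H <- t(vapply(warped, function(im) hog_descriptor(im, config$hog),
                      numeric(hog_length(config$hog))))
        rownames(H) <- ids
        out$hog <- H
      }
    }
    out
  })

  results <- stage("evaluate", {
    res <- list()
    for (ds in config$descriptors) {
      for (tr in config$traits) {
        bl <- binarize_scores(stats::setNames(score_mat[, tr], ids),
                              config$binarize_fraction)
        sel <- match(bl$ids, ids)
        for (cl in names(config$classifiers)) {
          sd_ <- subseed(config$seed, ds, tr, cl)
          fx <- switch(ds,
            geometric = geometric_featurizer(landmark_sets[sel]),
            eigenfaces = eigen_featurizer(feats$warped[sel],
                                          config$variance_fraction),
            hog = feats$hog[sel, , drop = FALSE])
          cv <- if (is.function(fx))
            nfold_cv(fx, bl$labels, config$classifiers[[cl]],
                     n_folds = config$n_folds, seed = sd_,
                     level = config$level, n_samples = length(sel))
          else nfold_cv(fx, bl$labels, config$classifiers[[cl]],
                        n_folds = config$n_folds, seed = sd_,
                        level = config$level)
          res[[ds]][[tr]][[cl]] <- cv
        }
      }
      say("  descriptor ", ds, " evaluated")
    }
    res
  })

  analysis <- stage("correlate", {
    an <- list()
    # descriptor-pair predicted-label correlation (out-of-fold labels)
    cc <- config$correlation_classifier
    pairs <- utils::combn(config$descriptors, 2, simplify = FALSE)
    if (length(config$descriptors) >= 2L) {
      tab <- do.call(rbind, lapply(pairs, function(p) {
        data.frame(pair = paste(p, collapse = "-"),
                   trait = config$traits,
                   correlation = vapply(config$traits, function(tr) {
                     a <- results[[p[1]]][[tr]][[cc]]$predictions
                     b <- results[[p[2]]][[tr]][[cc]]$predictions
                     as.numeric(prediction_label_correlation(a, b))
                   }, numeric(1)), row.names = NULL)
      }))
      an$label_correlation <- tab
    }
    # geometric feature-trait correlation + importance maps
    if ("geometric" %in% config$descriptors) {
      ft <- descriptor_feature_table(nrow(feats$mean_shape))
      gm <- geometric_descriptor_matrix(landmark_sets, feats$mean_shape)
      an$importance <- list()
      an$kind_share <- list()
      for (tr in config$traits) {
        bl <- binarize_scores(stats::setNames(score_mat[, tr], ids),
                              config$binarize_fraction)
        sel <- match(bl$ids, ids)
        co <- feature_trait_correlation(gm$features[sel, , drop = FALSE],
                                        bl$labels)
        an$importance[[tr]] <- point_importance(co, ft,
                                                config$importance_threshold)
        an$kind_share[[tr]] <- angle_vs_distance_share(co, ft,
                                                       config$importance_threshold)
      }
    }
    if (length(config$traits) >= 2L && nrow(score_mat) >= 3L)
      an$trait_pca <- trait_pca_projection(score_mat)
    an
  })

  out <- structure(list(config = config, results = results,
                        analysis = analysis, ids = ids,
                        mean_shape = feats$mean_shape,
                        score_matrix = score_mat),
                   class = "facetraits_experiment")
  if (!is.null(out_dir))
    stage("write", write_experiment(out, out_dir, overwrite = overwrite))
  out
}

#' Accuracy table of an experiment (classifiers x traits)
#'
#' @param experiment A `facetraits_experiment`.
#' @param descriptor Which descriptor's table.
#' @param what `"pretty"` (mean (ci) strings), `"mean"` or `"ci"`.
#' @return data.frame, rows = classifiers, columns = traits.
#' @export
accuracy_table <- function(experiment, descriptor,
                           what = c("pretty", "mean", "ci")) {
  what <- match.arg(what)
  res <- experiment$results[[descriptor]]
  if (is.null(res)) stop("descriptor not evaluated: ", descriptor)
  cls <- names(experiment$config$classifiers)
  traits <- experiment$config$traits
  cell <- function(cl, tr) {
    cv <- res[[tr]][[cl]]
    switch(what,
           pretty = sprintf("%.2f (%.1f)", cv$mean_accuracy, cv$ci_half_width),
           mean = cv$mean_accuracy, ci = cv$ci_half_width)
  }
  tab <- matrix(unlist(lapply(traits, function(tr)
    lapply(cls, function(cl) cell(cl, tr)))), length(cls), length(traits),
    dimnames = list(cls, traits))
  as.data.frame(tab)
}

#' @export
print.facetraits_experiment <- function(x, ...) {
  cat("facetraits experiment:", length(x$ids), "faces;",
      paste(x$config$descriptors, collapse = ", "), "descriptors;",
      length(x$config$classifiers), "classifiers;",
      length(x$config$traits), "traits\n")
  for (ds in x$config$descriptors) {
    cat("\n--", ds, "mean accuracy (CI half-width) --\n")
    print(accuracy_table(x, ds))
  }
  invisible(x)
}

write_experiment <- function(experiment, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite)
    stop("output directory '", dir, "' exists; pass overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- experiment$config
  for (ds in cfg$descriptors) {
    utils::write.csv(accuracy_table(experiment, ds),
                     file.path(dir, paste0("accuracy_", ds, ".csv")))
    pred <- do.call(rbind, lapply(cfg$traits, function(tr)
      do.call(rbind, lapply(names(cfg$classifiers), function(cl) {
        cv <- experiment$results[[ds]][[tr]][[cl]]
        data.frame(descriptor = ds, trait = tr, classifier = cl,
                   id = names(cv$predictions), fold = unname(cv$fold),
                   label = unname(cv$predictions),
                   confidence = round(unname(cv$confidences), 6))
      }))))
    utils::write.csv(pred, file.path(dir, paste0("predictions_", ds, ".csv")),
                     row.names = FALSE)
  }
  an <- experiment$analysis
  if (!is.null(an$label_correlation))
    utils::write.csv(transform(an$label_correlation,
                               correlation = round(correlation, 6)),
                     file.path(dir, "label_correlation.csv"), row.names = FALSE)
  if (!is.null(an$importance)) {
    imp <- do.call(rbind, lapply(names(an$importance), function(tr)
      data.frame(trait = tr, landmark = rownames(experiment$mean_shape),
                 count = an$importance[[tr]]$counts,
                 normalized = round(an$importance[[tr]]$normalized, 6))))
    utils::write.csv(imp, file.path(dir, "point_importance.csv"),
                     row.names = FALSE)
    for (tr in names(an$importance))
      plot_point_importance(an$importance[[tr]], experiment$mean_shape,
                            file.path(dir, paste0("importance_", tr, ".png")))
  }
  manifest <- list(
    seed = cfg$seed, n_faces = length(experiment$ids),
    descriptors = cfg$descriptors, traits = cfg$traits,
    classifiers = names(cfg$classifiers), n_folds = cfg$n_folds,
    level = cfg$level, binarize_fraction = cfg$binarize_fraction,
    variance_fraction = cfg$variance_fraction,
    hog = unclass(cfg$hog), importance_threshold = cfg$importance_threshold,
    correlation_classifier = cfg$correlation_classifier,
    package_version = as.character(utils::packageVersion("facetraits")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
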
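# Second-level analyses: agreement between descriptors' predicted labels,
# feature-trait correlation, landmark importance maps, trait-space PCA and
# confidence ranking.

#' Correlation between two predicted ±1 label vectors
#'
#' Pearson correlation of two aligned ±1 vectors — the phi coefficient.
#' If either vector is constant the correlation is undefined; 0 is returned
#' with attribute `undefined = TRUE`.
#'
#' @param pred_a,pred_b ±1 vectors over the same samples, aligned (if named,
#'   names must match).
#' @return Numeric in [-1, 1], possibly with attribute `undefined`.
#' @export
prediction_label_correlation <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b) || length(pred_a) < 2L)
    stop("need two aligned vectors with at least 2 samples")
  if (!is.null(names(pred_a)) && !is.null(names(pred_b)) &&
      !identical(names(pred_a), names(pred_b)))
    stop("sample ids are misaligned")
  if (stats::sd(pred_a) == 0 || stats::sd(pred_b) == 0)
    return(structure(0, undefined = TRUE))
  stats::cor(as.numeric(pred_a), as.numeric(pred_b))
}

#' Per-feature correlation with a trait's labels
#'
#' Pearson correlation of each descriptor column with the ±1 label vector.
#' Constant columns get 0 and are flagged.
#'
#' @param descriptor_matrix n x D matrix (rows = selected samples).
#' @param labels ±1 vector of length n.
#' @return Numeric vector of length D with attribute `flagged` (logical:
#'   constant columns).
#' @export
feature_trait_correlation <- function(descriptor_matrix, labels) {
  X <- as.matrix(descriptor_matrix)
  if (nrow(X) != length(labels)) stop("dimension mismatch")
  y <- as.numeric(labels)
  sds <- apply(X, 2L, stats::sd)
  flagged <- sds == 0 | !is.finite(sds)
  r <- rep(0, ncol(X))
  if (stats::sd(y) > 0 && any(!flagged))
    r[!flagged] <- as.vector(stats::cor(X[, !flagged, drop = FALSE], y))
  r[!is.finite(r)] <- 0
  structure(r, flagged = flagged, names = colnames(X))
}

select_features <- function(coefficients, threshold,
                            type = c("quantile", "absolute")) {
  type <- match.arg(type)
  a <- abs(coefficients)
  if (type == "quantile") {
    if (threshold < 0 || threshold > 1) stop("quantile threshold in [0, 1]")
    cut <- stats::quantile(a, threshold, names = FALSE)
  } else cut <- threshold
  which(a >= cut)
}

#' Landmark importance map for a trait
#'
#' Selects the descriptor features whose |correlation| with the trait labels
#' passes the threshold and counts, per landmark, how often the landmark
#' participates in a selected feature (both endpoints count for pairwise
#' features, since a mean point shares the anatomical identity of its face
#' point).  Counts are normalized by their maximum.
#'
#' @param coefficients Per-feature correlations from
#'   [feature_trait_correlation()].
#' @param feature_table A [descriptor_feature_table()].
#' @param threshold Selection threshold: a |correlation| quantile
#'   (`type = "quantile"`, default 0.95 = top 5%) or an absolute cut.
#' @param type `"quantile"` or `"absolute"`.
#' @return Object of class `point_importance`: list with `trait` (NA unless
#'   set by the caller), `counts` (raw per-landmark), `normalized`,
#'   `selected` (feature indices), `threshold`, `type`.
#' @export
point_importance <- function(coefficients, feature_table, threshold = 0.95,
                             type = c("quantile", "absolute")) {
  type <- match.arg(type)
  if (length(coefficients) != nrow(feature_table))
    stop("coefficients do not match the feature table")
  sel <- select_features(coefficients, threshold, type)
  P <- max(feature_table$i, na.rm = TRUE)
  counts <- integer(P)
  if (length(sel) == 0L) {
    warning("no feature passed the selection threshold; empty importance map")
  } else {
    tab_i <- table(factor(feature_table$i[sel], levels = seq_len(P)))
    counts <- as.integer(tab_i)
    jj <- feature_table$j[sel]
    jj <- jj[!is.na(jj)]
    if (length(jj)) {
      tab_j <- table(factor(jj, levels = seq_len(P)))
      counts <- counts + as.integer(tab_j)
    }
  }
  normalized <- if (max(counts) > 0) counts / max(counts) else rep(0, P)
  structure(list(counts = counts, normalized = normalized, selected = sel,
                 threshold = threshold, type = type), class = "point_importance")
}

#' @export
print.point_importance <- function(x, ...) {
  cat("Landmark importance map:", length(x$selected), "features selected (",
      x$type, "threshold", x$threshold, ")\n")
  top <- order(x$normalized, decreasing = TRUE)[1:3]
  cat("top landmarks:", paste0(top, " (", round(x$normalized[top], 2), ")",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Share of angle vs distance features among selected features
#'
#' @inheritParams point_importance
#' @return List with `counts` (per kind), `share` (proportions over the
#'   selection), and `selected`.
#' @export
angle_vs_distance_share <- function(coefficients, feature_table,
                                    threshold = 0.95,
                                    type = c("quantile", "absolute")) {
  type <- match.arg(type)
  sel <- select_features(coefficients, threshold, type)
  if (length(sel) == 0L) warning("no feature passed the selection threshold")
  mask <- rep(FALSE, nrow(feature_table)); mask[sel] <- TRUE
  counts <- feature_kind_partition(feature_table, mask)
  share <- if (sum(counts) > 0) counts / sum(counts) else counts * 0
  list(counts = counts, share = share, selected = sel)
}

#' Principal components of the trait-score space
#'
#' Eigen-decomposition of the correlation matrix of the n x 9 trait-score
#' matrix; the first two components play the role of the valence and
#' dominance dimensions of trait judgment space.
#'
#' @param trait_score_matrix n x T matrix (columns = traits).
#' @return Object of class `trait_pca`: `rotation` (loadings), `projections`
#'   (n x 2, first two components), `variance_shares` (all retained
#'   components), `dropped` (zero-variance trait columns, flagged).
#' @export
trait_pca_projection <- function(trait_score_matrix) {
  X <- as.matrix(trait_score_matrix)
  if (nrow(X) < 3L) stop("need at least 3 faces for the trait PCA")
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  keep <- sds > 0
  if (sum(keep) < 2L) stop("fewer than 2 traits with variance")
  Z <- scale(X[, keep, drop = FALSE])
  ei <- eigen(stats::cor(X[, keep, drop = FALSE]), symmetric = TRUE)
  shares <- ei$values / sum(ei$values)
  proj <- Z %*% ei$vectors[, 1:2, drop = FALSE]
  colnames(proj) <- c("PC1", "PC2")
  structure(list(rotation = ei$vectors, projections = proj,
                 variance_shares = shares, dropped = dropped,
                 traits = colnames(X)[keep]), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait-space PCA over", length(x$traits), "traits; PC1/PC2 shares:",
      paste(round(100 * x$variance_shares[1:2], 1), collapse = "% / "), "%\n")
  if (length(x$dropped))
    cat("dropped zero-variance traits:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Rank a gallery of faces by classifier confidence
#'
#' Uses the real-valued support of a fitted bank classifier to order unseen
#' samples by how strongly they express the trait (class side +1 first).
#'
#' @param model A fitted `trait_clf` from [fit_classifier()].
#' @param descriptor_matrix n x D feature matrix; rownames are sample ids.
#' @return data.frame with `id`, `label`, `confidence`, `score` (signed
#'   support), ordered by decreasing score; ties broken by id.
#' @export
rank_by_confidence <- function(model, descriptor_matrix) {
  if (!inherits(model, "trait_clf")) stop("model must be a fitted trait_clf")
  X <- as.matrix(descriptor_matrix)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  pr <- predict(model, X)
  # signed support: confidence toward class +1
  score <- ifelse(pr$label == 1, pr$confidence, -pr$confidence)
  ord <- order(-score, ids)
  data.frame(id = ids[ord], label = pr$label[ord],
             confidence = pr$confidence[ord], score = score[ord],
             row.names = NULL)
}

#' Render an importance map over the mean face
#'
#' Draws circles at the landmark positions of the mean face, radius and
#' brightness proportional to the normalized importance counts, and writes
#' the overlay as a grayscale PNG.
#'
#' @param importance A [point_importance()] result.
#' @param mean_shape P x 2 landmark matrix.
#' @param path Output PNG path.
#' @param size Image side length.
#' @return `path`, invisibly.
#' @export
plot_point_importance <- function(importance, mean_shape, path, size = 64L) {
  img <- render_face(mean_shape, size)
  gr <- pixel_grid(size)
  for (p in order(importance$normalized)) {
    w <- importance$normalized[p]
    if (w <= 0) next
    r <- 1 + 3.5 * w
    m <- (gr$X - mean_shape[p, 1])^2 + (gr$Y - mean_shape[p, 2])^2 <= r^2
    img[m] <- 0.5 + 0.5 * w
  }
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
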
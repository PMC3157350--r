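# Trait binarization, stratified N-fold cross-validation and the
# Student-t confidence interval on fold accuracies.

#' Binarize continuous trait scores
#'
#' Ranks the scores and labels the top `fraction` of samples as *class* (+1)
#' and the bottom `fraction` as *no class* (-1); the middle ranks are
#' discarded to reduce the influence of mislabeled or borderline samples.
#' Ties are broken by stable sample-id order.
#'
#' @param scores Named numeric vector (names = sample ids) or unnamed (ids
#'   are then positional).
#' @param fraction Fraction per side, in (0, 0.5].
#' @return Object of class `binary_labels`: list with `ids` (selected, in
#'   original order), `labels` (±1 named by id), `discarded` (ids), and
#'   `fraction`.
#' @export
binarize_scores <- function(scores, fraction = 1 / 3) {
  if (fraction <= 0 || fraction > 0.5)
    stop("config error: fraction must be in (0, 0.5]")
  n <- length(scores)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- ceiling(fraction * n)
  if (2L * m > n) m <- floor(n / 2)
  if (m < 1L) stop("too few samples to binarize")
  ord <- order(scores, seq_len(n))          # ascending; ties by id order
  low <- ord[seq_len(m)]
  high <- ord[seq(n - m + 1L, n)]
  sel <- sort(c(low, high))
  labels <- ifelse(sel %in% high, 1, -1)
  names(labels) <- ids[sel]
  structure(list(ids = ids[sel], labels = labels,
                 discarded = ids[setdiff(seq_len(n), sel)],
                 fraction = fraction), class = "binary_labels")
}

# stratified fold assignment: splits each class separately, preserving class
# balance per fold where divisible; uses the current RNG stream
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Confidence-interval half-width on fold accuracies
#'
#' `t * s / sqrt(N)` with `s` the sample standard deviation of the fold
#' accuracies and `t` the Student-t quantile at `(1 + level)/2` with `N - 1`
#' degrees of freedom (or the normal quantile with `multiplier = "z"`).
#'
#' @param fold_accuracies Numeric vector of per-fold accuracies (>= 2).
#' @param level Confidence level in (0, 1).
#' @param multiplier `"t"` (default) or `"z"`.
#' @return Half-width, same units as the accuracies.
#' @export
confidence_interval <- function(fold_accuracies, level = 0.95,
                                multiplier = c("t", "z")) {
  multiplier <- match.arg(multiplier)
  N <- length(fold_accuracies)
  if (N < 2L) stop("confidence interval undefined for fewer than 2 folds")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  s <- stats::sd(fold_accuracies)
  q <- if (multiplier == "t") stats::qt((1 + level) / 2, df = N - 1L)
       else stats::qnorm((1 + level) / 2)
  q * s / sqrt(N)
}

#' Stratified N-fold cross-validation of one classifier on one trait
#'
#' @param features n x D feature matrix (rows aligned with `labels`), or a
#'   featurizer `function(train_idx, test_idx)` returning
#'   `list(train = matrix, test = matrix)` — used when part of the descriptor
#'   (mean shape, eigen basis) must be fit on the training fold only.
#' @param labels ±1 vector (named by sample id, optional).
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment and any classifier
#'   randomness.
#' @param level Confidence level for the interval.
#' @param n_samples Required when `features` is a function: number of samples.
#' @return Object of class `trait_cv`.
#' @export
nfold_cv <- function(features, labels, spec, n_folds = 10L, seed = 1L,
                     level = 0.95, n_samples = NULL) {
  featurizer <- NULL
  if (is.function(features)) {
    featurizer <- features
    n <- n_samples
    if (is.null(n)) stop("n_samples required with a featurizer")
  } else {
    features <- as.matrix(features)
    n <- nrow(features)
  }
  if (length(labels) != n) stop("labels length does not match features")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > min(table(labels))) stop("n_folds exceeds the smaller class")
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds)
    acc <- numeric(n_folds)
    pred <- numeric(n)
    conf <- numeric(n)
    for (fl in seq_len(n_folds)) {
      te <- fold == fl
      if (is.null(featurizer)) {
        xtr <- features[!te, , drop = FALSE]
        xte <- features[te, , drop = FALSE]
      } else {
        fx <- featurizer(which(!te), which(te))
        xtr <- fx$train; xte <- fx$test
      }
      out <- classifier_bank(spec, list(x = xtr, y = labels[!te]), xte)
      pred[te] <- out$label
      conf[te] <- out$confidence
      acc[fl] <- 100 * mean(out$label == labels[te])
    }
    structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                   ci_half_width = confidence_interval(acc, level),
                   predictions = stats::setNames(pred, ids),
                   confidences = stats::setNames(conf, ids),
                   fold = stats::setNames(fold, ids), spec = spec,
                   n_folds = n_folds, level = level, seed = seed),
              class = "trait_cv")
  })
}

#' @export
print.trait_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV [%s]: mean accuracy %.2f%% (± %.2f, %d%% level)\n",
              x$n_folds, x$spec$method, x$mean_accuracy, x$ci_half_width,
              round(100 * x$level)))
  invisible(x)
}

#' @export
summary.trait_cv <- function(object, ...) {
  print(object)
  cat("fold accuracies:", paste(sprintf("%.1f", object$fold_accuracies),
                                collapse = " "), "\n")
  invisible(object)
}
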
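# Five-classifier bank.  Each method is fit through fit_classifier() which
# freezes per-feature z-scoring on the training data; every fitted object
# answers predict() with a ±1 label and a real-valued confidence (margin,
# vote share or posterior).

col_cumsum <- function(M) {
  n <- nrow(M); F <- ncol(M)
  cs <- matrix(cumsum(as.vector(M)), n, F)
  if (F > 1L)
    cs <- cs - matrix(rep(c(0, cs[n, -F]), each = n), n, F)
  cs
}

#' GentleBoost with regression stumps
#'
#' Additive boosting: each iteration fits the weighted-least-squares
#' regression stump (feature, threshold, two leaf values) minimizing weighted
#' squared error against the ±1 labels, adds it to the additive score, and
#' re-weights examples by `w * exp(-y * f(x))`.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Labels in {-1, +1}.
#' @param n_iter Boosting iterations.
#' @return Object of class `gentleboost` with the stump table and the
#'   exponential-loss path.
#' @export
gentleboost <- function(X, y, n_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); F <- ncol(X)
  if (length(unique(y)) < 2L)
    stop("single-class training data; boosting needs both labels")
  stopifnot(all(y %in% c(-1, 1)), n_iter >= 1L)
  ord <- apply(X, 2L, order)
  flat <- as.vector(ord) + rep((seq_len(F) - 1L) * n, each = n)
  Xs <- matrix(X[flat], n, F)
  splittable <- Xs[-n, , drop = FALSE] != Xs[-1L, , drop = FALSE]
  thr_mid <- (Xs[-n, , drop = FALSE] + Xs[-1L, , drop = FALSE]) / 2
  w <- rep(1 / n, n)
  Fx <- numeric(n)
  stumps <- data.frame(feature = integer(n_iter), threshold = numeric(n_iter),
                       left = numeric(n_iter), right = numeric(n_iter))
  loss <- numeric(n_iter)
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    wy <- w * y
    Ws <- matrix(w[ord], n, F)
    Ss <- matrix(wy[ord], n, F)
    cumW <- col_cumsum(Ws)[-n, , drop = FALSE]
    cumS <- col_cumsum(Ss)[-n, , drop = FALSE]
    totS <- sum(wy)
    WL <- cumW; SL <- cumS
    WR <- 1 - WL; SR <- totS - SL
    gain <- SL^2 / pmax(WL, eps) + SR^2 / pmax(WR, eps)
    gain[!splittable] <- -Inf
    best <- which.max(gain)
    k <- (best - 1L) %% (n - 1L) + 1L
    f <- (best - 1L) %/% (n - 1L) + 1L
    thr <- thr_mid[k, f]
    left <- SL[k, f] / max(WL[k, f], eps)
    right <- SR[k, f] / max(WR[k, f], eps)
    fx <- ifelse(X[, f] <= thr, left, right)
    Fx <- Fx + fx
    w <- w * exp(-y * fx)
    loss[it] <- mean(exp(-y * Fx))
    w <- w / sum(w)
    stumps$feature[it] <- f; stumps$threshold[it] <- thr
    stumps$left[it] <- left; stumps$right[it] <- right
  }
  structure(list(stumps = stumps, n_iter = n_iter, loss = loss,
                 train_score = Fx), class = "gentleboost")
}

#' @export
predict.gentleboost <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  score <- numeric(nrow(X))
  st <- object$stumps
  for (it in seq_len(nrow(st)))
    score <- score + ifelse(X[, st$feature[it]] <= st$threshold[it],
                            st$left[it], st$right[it])
  data.frame(label = ifelse(score >= 0, 1, -1), confidence = score)
}

#' @export
print.gentleboost <- function(x, ...) {
  cat("GentleBoost model:", x$n_iter, "stumps over",
    length(unique(x$stumps$feature)), "distinct features; final exp-loss",
    signif(x$loss[x$n_iter], 4), "\n")
  invisible(x)
}

# ---- k-nearest neighbours ------------------------------------------------

knn_fit <- function(X, y, k = 5L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  structure(list(X = as.matrix(X), y = y, k = k), class = "knn_fit")
}

#' @export
predict.knn_fit <- function(object, newdata, ...) {
  Xt <- as.matrix(newdata)
  tr <- object$X
  k <- object$k
  d2 <- outer(rowSums(Xt^2), rowSums(tr^2), `+`) - 2 * tcrossprod(Xt, tr)
  lab <- numeric(nrow(Xt)); conf <- numeric(nrow(Xt))
  for (i in seq_len(nrow(Xt))) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]  # distance tie: lower id
    votes <- object$y[nb]
    share <- mean(votes == 1)
    lab[i] <- if (share > 0.5) 1 else -1
    conf[i] <- max(share, 1 - share)
  }
  data.frame(label = lab, confidence = conf)
}

# ---- Parzen windows + random subspaces -----------------------------------

silverman_bw <- function(X) {
  # per-column Silverman rule: 0.9 min(sd, IQR/1.34) n^(-1/5), floored
  n <- nrow(X)
  mu <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2L, mu)^2) / max(n - 1L, 1L))
  q <- apply(X, 2L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- (q[2L, ] - q[1L, ]) / 1.34
  spread <- pmin(s, ifelse(iqr > 0, iqr, s))
  pmax(0.9 * spread * n^(-1 / 5), 1e-3)
}

parzen_rs_fit <- function(X, y, M = 25L, rho = 0.5) {
  X <- as.matrix(X)
  if (rho <= 0 || rho > 1) stop("subspace fraction rho must be in (0, 1]")
  d <- ncol(X)
  m <- max(1L, ceiling(rho * d))
  subspaces <- lapply(seq_len(M), function(i)
    if (m == d) seq_len(d) else sort(sample.int(d, m)))
  pos <- y == 1
  structure(list(X = X, y = y, subspaces = subspaces, M = M, rho = rho,
                 bw_pos = silverman_bw(X[pos, , drop = FALSE]),
                 bw_neg = silverman_bw(X[!pos, , drop = FALSE])),
            class = "parzen_rs")
}

parzen_log_density <- function(train, test, bw) {
  # mean of Gaussian product kernels; constant factors cancel between classes
  # only if bandwidths matched, so keep them: log density up to the common
  # (2*pi)^(-d/2) factor.
  z <- sweep(test, 2L, bw, `/`)
  t2 <- sweep(train, 2L, bw, `/`)
  d2 <- outer(rowSums(z^2), rowSums(t2^2), `+`) - 2 * tcrossprod(z, t2)
  d2[d2 < 0] <- 0
  K <- exp(-0.5 * d2)
  log(pmax(rowMeans(K), 1e-300)) - sum(log(bw))
}

#' @export
predict.parzen_rs <- function(object, newdata, ...) {
  Xt <- as.matrix(newdata)
  votes <- matrix(0, nrow(Xt), object$M)
  pos <- object$y == 1
  for (s in seq_along(object$subspaces)) {
    idx <- object$subspaces[[s]]
    trp <- object$X[pos, idx, drop = FALSE]
    trn <- object$X[!pos, idx, drop = FALSE]
    te <- Xt[, idx, drop = FALSE]
    lp <- parzen_log_density(trp, te, object$bw_pos[idx])
    ln <- parzen_log_density(trn, te, object$bw_neg[idx])
    votes[, s] <- ifelse(lp >= ln, 1, -1)
  }
  share <- rowMeans(votes == 1)
  lab <- ifelse(share >= 0.5, 1, -1)
  data.frame(label = lab, confidence = pmax(share, 1 - share))
}

# ---- SVM (RBF) and decision tree wrappers --------------------------------

svm_rbf_fit <- function(X, y, tune = TRUE, inner_folds = 3L,
                        cost_grid = c(1, 10, 100),
                        gamma_scale_grid = c(0.5, 1, 2)) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(-1, 1))
  gamma0 <- 1 / ncol(X)
  best <- c(cost = cost_grid[1L], gamma = gamma0)
  if (tune && length(y) >= 2L * inner_folds) {
    folds <- stratified_folds(y, inner_folds)
    acc_best <- -1
    for (co in cost_grid) for (gs in gamma_scale_grid) {
      ga <- gs * gamma0
      acc <- 0
      for (fl in seq_len(inner_folds)) {
        te <- folds == fl
        if (length(unique(y[!te])) < 2L) next
        m <- e1071::svm(X[!te, , drop = FALSE], yf[!te], kernel = "radial",
                        cost = co, gamma = ga, scale = FALSE)
        acc <- acc + mean(predict(m, X[te, , drop = FALSE]) == yf[te])
      }
      if (acc > acc_best + 1e-12) { acc_best <- acc; best <- c(cost = co, gamma = ga) }
    }
  }
  model <- e1071::svm(X, yf, kernel = "radial", cost = best["cost"],
                      gamma = best["gamma"], scale = FALSE)
  structure(list(model = model, cost = unname(best["cost"]),
                 gamma = unname(best["gamma"])), class = "svm_rbf_fit")
}

#' @export
predict.svm_rbf_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  pr <- predict(object$model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient the margin so positive means class +1
  pos_first <- startsWith(colnames(dv)[1L], "1")
  margin <- if (pos_first) dv[, 1L] else -dv[, 1L]
  data.frame(label = as.numeric(as.character(pr)), confidence = margin)
}

tree_fit <- function(X, y) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.cls <- factor(y, levels = c(-1, 1))
  fit <- rpart::rpart(.cls ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = 0.001, xval = 5,
                                                     minsplit = 4))
  cptab <- fit$cptable
  best_cp <- cptab[which.min(cptab[, "xerror"]), "CP"]
  structure(list(model = rpart::prune(fit, cp = best_cp)), class = "tree_fit")
}

#' @export
predict.tree_fit <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- paste0("f", seq_len(ncol(df)))
  pp <- predict(object$model, df, type = "prob")
  p1 <- pp[, "1"]
  data.frame(label = ifelse(p1 >= 0.5, 1, -1),
             confidence = pmax(p1, 1 - p1))
}

# ---- bank interface ------------------------------------------------------

#' Specification of one classifier in the bank
#'
#' @param method One of `"gentleboost"`, `"svm_rbf"`, `"tree"`, `"knn"`,
#'   `"parzen_rs"`.
#' @param ... Method hyperparameters: `n_iter` (gentleboost, default 100);
#'   `k` (knn, odd, default 5); `M`, `rho` (parzen_rs, defaults 25, 0.5);
#'   `tune` (svm_rbf, default TRUE).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(method = c("gentleboost", "svm_rbf", "tree",
                                       "knn", "parzen_rs"), ...) {
  method <- match.arg(method)
  pars <- list(...)
  defaults <- switch(method,
    gentleboost = list(n_iter = 100L),
    svm_rbf = list(tune = TRUE),
    tree = list(),
    knn = list(k = 5L),
    parzen_rs = list(M = 25L, rho = 0.5))
  pars <- utils::modifyList(defaults, pars)
  if (method == "knn" && (pars$k < 1L || pars$k %% 2L != 1L))
    stop("knn k must be odd and >= 1")
  if (method == "gentleboost" && pars$n_iter < 1L)
    stop("gentleboost n_iter must be >= 1")
  if (method == "parzen_rs" && (pars$rho <= 0 || pars$rho > 1))
    stop("parzen_rs rho must be in (0, 1]")
  structure(list(method = method, params = pars), class = "classifier_spec")
}

#' Fit one classifier of the bank (with frozen feature scaling)
#'
#' Per-feature z-scoring is fitted on the training data and stored in the
#' returned object, so test data are standardized with training statistics.
#'
#' @param spec A [classifier_spec()].
#' @param X Training feature matrix.
#' @param y Training labels in {-1, +1}.
#' @return Object of class `trait_clf`.
#' @export
fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, `/`)
  p <- spec$params
  model <- switch(spec$method,
    gentleboost = gentleboost(Xs, y, n_iter = p$n_iter),
    svm_rbf = svm_rbf_fit(Xs, y, tune = p$tune),
    tree = tree_fit(Xs, y),
    knn = knn_fit(Xs, y, k = p$k),
    parzen_rs = parzen_rs_fit(Xs, y, M = p$M, rho = p$rho))
  structure(list(spec = spec, model = model, mu = mu, sd = sd_),
            class = "trait_clf")
}

#' @export
predict.trait_clf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$mu))
    stop("test feature dimension (", ncol(X), ") does not match training (",
         length(object$mu), ")")
  Xs <- sweep(sweep(X, 2L, object$mu), 2L, object$sd, `/`)
  predict(object$model, Xs)
}

#' @export
print.trait_clf <- function(x, ...) {
  cat("Fitted bank classifier:", x$spec$method, "on",
      length(x$mu), "features\n")
  invisible(x)
}

#' Train on one split and predict another
#'
#' @param spec A [classifier_spec()].
#' @param train List with `x` (matrix) and `y` (±1 labels).
#' @param test Feature matrix of test samples.
#' @return data.frame with `label` (±1) and `confidence` per test row.
#' @export
classifier_bank <- function(spec, train, test) {
  fit <- fit_classifier(spec, train$x, train$y)
  predict(fit, test)
}
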
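# Holistic appearance descriptors computed on shape-normalized images:
# an eigen-decomposition (EigenFaces) representation and a dense-grid
# histogram of oriented gradients (HOG) with unsigned gradients.

#' Fit an eigen-decomposition (EigenFaces) model
#'
#' PCA of vectorized images; retains the smallest number of components whose
#' cumulative eigenvalue share reaches `variance_fraction`.
#'
#' @param images List of equal-size image matrices (>= 2).
#' @param variance_fraction Fraction of variance to retain, in (0, 1].
#' @return An object of class `eigenfaces`: list with `mean` (mean image
#'   vector), `components` (d x k orthonormal columns), `eigenvalues` (all),
#'   `k`, `variance_fraction`, `dim` (image dimensions).
#' @export
fit_eigenfaces <- function(images, variance_fraction = 0.95) {
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("config error: variance_fraction must be in (0, 1]")
  if (length(images) < 2L) stop("need at least 2 images")
  dm <- dim(images[[1L]])
  X <- t(vapply(images, function(im) {
    if (!identical(dim(im), dm)) stop("images must share one size")
    as.vector(im)
  }, numeric(prod(dm))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (nrow(X) - 1L)
  pos <- ev > max(ev) * 1e-12
  share <- cumsum(ev) / sum(ev)
  k <- which(share >= variance_fraction - 1e-12)[1L]
  k <- min(k, sum(pos))
  structure(list(mean = mu, components = sv$v[, seq_len(k), drop = FALSE],
                 eigenvalues = ev, k = k,
                 variance_fraction = variance_fraction, dim = dm),
            class = "eigenfaces")
}

#' @export
print.eigenfaces <- function(x, ...) {
  cat("EigenFaces model: ", x$k, " components retained (",
      round(100 * sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues), 1),
      "% of variance), image ", paste(x$dim, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Project an image onto an eigenfaces basis
#'
#' @param model An [fit_eigenfaces()] model.
#' @param image Image matrix (or already-vectorized numeric).
#' @return Numeric coefficient vector of length `model$k`.
#' @export
project_eigenfaces <- function(model, image) {
  v <- as.vector(image)
  if (length(v) != length(model$mean))
    stop("image size mismatch: got ", length(v), " pixels, model expects ",
         length(model$mean))
  as.vector(crossprod(model$components, v - model$mean))
}

#' HOG parameterization
#'
#' @param window Window side length, pixels (images are `window x window`).
#' @param cell Cell side length, pixels; must divide `window`.
#' @param block Block side length, cells.
#' @param overlap Block overlap, cells; must be smaller than `block`.
#' @param n_bins Orientation bins evenly spaced over 180 degrees (unsigned
#'   gradients).
#' @param epsilon Block L2-normalization constant.
#' @return A validated `hog_params` list.
#' @export
hog_params <- function(window = 64L, cell = 8L, block = 2L, overlap = 1L,
                       n_bins = 9L, epsilon = 1e-6) {
  if (window %% cell != 0L)
    stop("config error: window (", window, ") not divisible by cell (", cell, ")")
  if (overlap >= block) stop("config error: overlap must be < block")
  if (n_bins < 1L) stop("config error: n_bins must be >= 1")
  structure(list(window = as.integer(window), cell = as.integer(cell),
                 block = as.integer(block), overlap = as.integer(overlap),
                 n_bins = as.integer(n_bins), epsilon = epsilon),
            class = "hog_params")
}

#' Length of the HOG descriptor for a parameterization
#'
#' Blocks slide with stride `block - overlap` cells over the cell grid; each
#' contributes `block^2 * n_bins` values.
#'
#' @param params A [hog_params()].
#' @return Integer descriptor length.
#' @export
hog_length <- function(params) {
  nc <- params$window %/% params$cell
  stride <- params$block - params$overlap
  nb <- (nc - params$block) %/% stride + 1L
  as.integer(nb * nb * params$block^2 * params$n_bins)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Per-pixel gradients by central differences with replicate padding;
#' orientations folded to [0, 180) (unsigned); magnitude-weighted cell
#' histograms with linear interpolation between adjacent orientation bins;
#' overlapping blocks of cells concatenated and L2-normalized.
#'
#' @param image `window x window` image matrix.
#' @param params A [hog_params()].
#' @return Numeric descriptor of length [hog_length()].
#' @export
hog_descriptor <- function(image, params = hog_params()) {
  W <- params$window
  if (!all(dim(image) == W))
    stop("image must be ", W, "x", W, " for this parameterization")
  # replicate-padded central differences; image[r, c]: x along columns
  gx <- (image[, c(2:W, W)] - image[, c(1, 1:(W - 1))]) / 2
  gy <- (image[c(2:W, W), ] - image[c(1, 1:(W - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180  # unsigned

  nb <- params$n_bins
  bw <- 180 / nb
  # linear interpolation between the two nearest bin centers (circular /180)
  pos <- ang / bw - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  bin0 <- (b0 %% nb) + 1L
  bin1 <- ((b0 + 1) %% nb) + 1L

  nc <- W %/% params$cell
  cell_row <- ((row(image) - 1L) %/% params$cell) + 1L
  cell_col <- ((col(image) - 1L) %/% params$cell) + 1L
  cell_id <- cell_row + (cell_col - 1L) * nc
  # accumulate magnitude into (cell, bin); key is column-major into H
  ncells <- nc * nc
  Hvec <- numeric(ncells * nb)
  key0 <- as.vector(cell_id) + (as.vector(bin0) - 1L) * ncells
  key1 <- as.vector(cell_id) + (as.vector(bin1) - 1L) * ncells
  acc0 <- tapply(as.vector(mag * (1 - w1)), key0, sum)
  acc1 <- tapply(as.vector(mag * w1), key1, sum)
  Hvec[as.integer(names(acc0))] <- Hvec[as.integer(names(acc0))] + acc0
  Hvec[as.integer(names(acc1))] <- Hvec[as.integer(names(acc1))] + acc1
  H <- matrix(Hvec, ncells, nb)

  stride <- params$block - params$overlap
  nbk <- (nc - params$block) %/% stride + 1L
  cell_at <- function(r, c) H[r + (c - 1L) * nc, ]
  blocks <- vector("list", nbk * nbk)
  bi <- 1L
  for (bc in seq_len(nbk)) {
    for (br in seq_len(nbk)) {
      r0 <- (br - 1L) * stride + 1L
      c0 <- (bc - 1L) * stride + 1L
      v <- unlist(lapply(seq(c0, length.out = params$block), function(cc)
        lapply(seq(r0, length.out = params$block), function(rr) cell_at(rr, cc))),
        use.names = FALSE)
      blocks[[bi]] <- v / sqrt(sum(v^2) + params$epsilon^2)
      bi <- bi + 1L
    }
  }
  unlist(blocks, use.names = FALSE)
}
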
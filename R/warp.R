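# Shape normalization: warp each face so its landmarks coincide with a
# reference configuration, isolating appearance from structure.  The warp is
# piecewise affine over a Delaunay triangulation of the reference landmarks
# plus 8 fixed border anchors.

#' Choose the reference face for shape normalization
#'
#' The reference is the training face whose landmarks minimize the summed
#' point distance to the mean shape, balancing the deformation the remaining
#' faces undergo.
#'
#' @param landmark_sets List of P x 2 landmark matrices.
#' @param mean_shape Optional mean shape (computed from the sets if missing).
#' @return List with `index` (position in `landmark_sets`), `shape`, and
#'   `distance` (the winning summed distance).
#' @export
choose_reference <- function(landmark_sets, mean_shape = NULL) {
  if (is.null(mean_shape)) mean_shape <- compute_mean_shape(landmark_sets)
  d <- vapply(landmark_sets, function(lm)
    sum(sqrt(rowSums((lm - mean_shape)^2))), numeric(1))
  i <- which.min(d)
  list(index = i, shape = landmark_sets[[i]], distance = d[i])
}

# Bowyer-Watson Delaunay triangulation.  A tiny deterministic jitter breaks
# the cocircular degeneracies of the symmetric landmark template; triangle
# indices refer to the original (unjittered) points.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate")
  p <- pts + 1e-4 * cbind(cos(seq_len(n) * 2.399963), sin(seq_len(n) * 1.732051))
  # super-triangle
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  M <- max(diff(range(p[, 1])), diff(range(p[, 2]))) * 10 + 10
  p <- rbind(p, c(cx - 2 * M, cy - M), c(cx + 2 * M, cy - M), c(cx, cy + 2 * M))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1L, 3L)
  circum <- function(t) {
    a <- p[t[1L], ]; b <- p[t[2L], ]; c_ <- p[t[3L], ]
    d <- 2 * (a[1] * (b[2] - c_[2]) + b[1] * (c_[2] - a[2]) + c_[1] * (a[2] - b[2]))
    ux <- ((sum(a^2)) * (b[2] - c_[2]) + (sum(b^2)) * (c_[2] - a[2]) +
             (sum(c_^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c_[1] - b[1]) + (sum(b^2)) * (a[1] - c_[1]) +
             (sum(c_^2)) * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }
  cc <- matrix(circum(tris[1L, ]), 1L, 3L, byrow = TRUE)
  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    bad <- which((px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    # boundary polygon = edges of bad triangles not shared by two bad triangles
    edges <- NULL
    for (t in bad) {
      tv <- tris[t, ]
      edges <- rbind(edges, tv[c(1L, 2L)], tv[c(2L, 3L)], tv[c(3L, 1L)])
    }
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(edges, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1L, circum)))
  }
  keep <- apply(tris, 1L, function(t) all(t <= n))
  unname(tris[keep, , drop = FALSE])
}

border_anchors <- function(size) {
  s <- size - 1
  m <- s / 2
  cbind(x = c(0, m, s, 0, s, 0, m, s),
        y = c(0, 0, 0, m, m, s, s, s))
}

bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  at <- function(r, c) img[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x1) +
    (1 - fx) * fy * at(y1, x0) + fx * fy * at(y1, x1)
}

#' Warp a face image onto a reference landmark configuration
#'
#' Piecewise-affine warp driven by a Delaunay triangulation of the reference
#' landmarks plus 8 border anchors.  Source landmarks map exactly onto the
#' reference positions (triangle vertices are interpolated exactly); the
#' output has the reference image size.
#'
#' @param image Source image matrix (values in [0, 1]).
#' @param landmarks P x 2 landmarks of the source face.
#' @param reference_shape P x 2 reference landmark configuration.
#' @param size Output side length (reference image size); defaults to the
#'   source size.
#' @return Warped image matrix of dimension `size` x `size`.
#' @export
shape_normalize <- function(image, landmarks, reference_shape,
                            size = nrow(image)) {
  if (nrow(landmarks) != nrow(reference_shape))
    stop("landmarks and reference_shape must share the point template")
  anc_ref <- border_anchors(size)
  anc_src <- border_anchors(nrow(image))
  ref <- rbind(unname(reference_shape), unname(anc_ref))
  src <- rbind(unname(landmarks), unname(anc_src))
  tri <- delaunay_triangulate(ref)
  gr <- pixel_grid(size)
  Xo <- as.vector(gr$X); Yo <- as.vector(gr$Y)
  sx <- rep(NA_real_, length(Xo)); sy <- rep(NA_real_, length(Yo))
  done <- rep(FALSE, length(Xo))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    r1 <- ref[v[1L], ]; r2 <- ref[v[2L], ]; r3 <- ref[v[3L], ]
    det <- (r2[1] - r1[1]) * (r3[2] - r1[2]) - (r3[1] - r1[1]) * (r2[2] - r1[2])
    s1 <- src[v[1L], ]; s2 <- src[v[2L], ]; s3 <- src[v[3L], ]
    sdet <- (s2[1] - s1[1]) * (s3[2] - s1[2]) - (s3[1] - s1[1]) * (s2[2] - s1[2])
    if (abs(sdet) < 1e-9)
      stop("degenerate (collinear) source triangle over points ",
           paste(v, collapse = "-"))
    l2 <- ((Xo - r1[1]) * (r3[2] - r1[2]) - (Yo - r1[2]) * (r3[1] - r1[1])) / det
    l3 <- ((Yo - r1[2]) * (r2[1] - r1[1]) - (Xo - r1[1]) * (r2[2] - r1[2])) / det
    l1 <- 1 - l2 - l3
    m <- !done & l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(m)) next
    sx[m] <- l1[m] * s1[1] + l2[m] * s2[1] + l3[m] * s3[1]
    sy[m] <- l1[m] * s1[2] + l2[m] * s2[2] + l3[m] * s3[2]
    done[m] <- TRUE
  }
  if (!all(done)) {  # numerically orphaned pixels: sample at their own position
    sx[!done] <- Xo[!done]; sy[!done] <- Yo[!done]
  }
  matrix(bilinear_sample(image, sx, sy), size, size)
}
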
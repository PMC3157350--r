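#' Mean landmark configuration over a face set
#'
#' Coordinate-wise arithmetic mean of a list of landmark sets, all sharing the
#' same point count and anatomical ordering.
#'
#' @param landmark_sets List of P x 2 landmark matrices.
#' @return A P x 2 matrix (the mean shape), keeping the rownames of the first
#'   set.
#' @export
compute_mean_shape <- function(landmark_sets) {
  if (!is.list(landmark_sets) || length(landmark_sets) < 1L)
    stop("need at least one landmark set")
  P <- nrow(landmark_sets[[1L]])
  for (s in landmark_sets) {
    if (!is.matrix(s) || ncol(s) != 2L || nrow(s) != P)
      stop("shape mismatch: all landmark sets must be P x 2 with P = ", P)
  }
  m <- Reduce(`+`, landmark_sets) / length(landmark_sets)
  dimnames(m) <- dimnames(landmark_sets[[1L]])
  m
}

#' Polar difference between two points
#'
#' Radius is the Euclidean norm of `p - q`; angle is `atan2(dy, dx)` in
#' radians in (-pi, pi], measured in image coordinates (y downward).  The
#' angle of a zero-radius difference is defined as 0.
#'
#' @param p,q Numeric length-2 vectors (x, y).
#' @return Numeric vector `c(radius, angle)`.
#' @export
polar_diff <- function(p, q) {
  d <- p - q
  r <- sqrt(sum(d^2))
  a <- if (r == 0) 0 else atan2(d[2L], d[1L])
  c(radius = r, angle = unname(a))
}

#' Feature table for the geometric descriptor
#'
#' Enumerates, for a P-point template, every entry of the structural feature
#' vector: set 1 (each point relative to its own mean position, radius and
#' angle), set 2 (each face point relative to every mean point, radius and
#' angle, row-major in face point then mean point), and set 3 (within-face
#' Euclidean distances over pairs i < j, lexicographic).  Feature names follow
#' `s1_r_05`, `s2_a_03_17`, `s3_d_02_09` (1-based, zero-padded indices).
#'
#' @param P Number of landmarks (default 21).
#' @return A data.frame with columns `name`, `set`, `kind` (radius / angle /
#'   distance), `i`, `j` (`NA` for set 1).  Row order is the descriptor order.
#' @export
descriptor_feature_table <- function(P = 21L) {
  P <- as.integer(P)
  if (P < 2L) stop("P must be >= 2")
  z <- function(k) formatC(k, width = 2, flag = "0")
  # set 1: per point, (radius, angle) to its own mean position
  i1 <- rep(seq_len(P), each = 2L)
  k1 <- rep(c("radius", "angle"), P)
  n1 <- paste0("s1_", ifelse(k1 == "radius", "r", "a"), "_", z(i1))
  # set 2: row-major (i over face points, j over mean points), (radius, angle)
  i2 <- rep(seq_len(P), each = 2L * P)
  j2 <- rep(rep(seq_len(P), each = 2L), P)
  k2 <- rep(c("radius", "angle"), P * P)
  n2 <- paste0("s2_", ifelse(k2 == "radius", "r", "a"), "_", z(i2), "_", z(j2))
  # set 3: unordered pairs i < j, lexicographic
  pr <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  n3 <- paste0("s3_d_", z(pr[, 1L]), "_", z(pr[, 2L]))
  data.frame(
    name = c(n1, n2, n3),
    set  = rep(c(1L, 2L, 3L), c(2L * P, 2L * P * P, nrow(pr))),
    kind = c(k1, k2, rep("distance", nrow(pr))),
    i    = c(i1, i2, pr[, 1L]),
    j    = c(rep(NA_integer_, 2L * P), j2, pr[, 2L]),
    stringsAsFactors = FALSE
  )
}

#' Structural (geometric) descriptor of a face
#'
#' Builds the three-part structural feature vector from a landmark set and a
#' mean shape: polar differences of each point to its mean position, polar
#' relations of each face point to all mean points, and all within-face
#' inter-point distances.  Length is 2P + 2P^2 + P(P-1)/2 (1134 at P = 21).
#'
#' @param landmarks P x 2 landmark matrix.
#' @param mean_shape P x 2 mean shape with the same ordering.
#' @param feature_table Optional precomputed [descriptor_feature_table()]
#'   for this P (saves recomputation in loops).
#' @return An object of class `geom_descriptor`: a named numeric vector with
#'   attribute `feature_table`.
#' @export
geometric_descriptor <- function(landmarks, mean_shape,
                                 feature_table = NULL) {
  if (!is.matrix(landmarks) || !is.matrix(mean_shape) ||
      ncol(landmarks) != 2L || ncol(mean_shape) != 2L ||
      nrow(landmarks) != nrow(mean_shape))
    stop("shape mismatch: landmarks and mean_shape must be P x 2 with equal P")
  P <- nrow(landmarks)
  if (is.null(feature_table)) feature_table <- descriptor_feature_table(P)

  # set 1
  d1 <- landmarks - mean_shape
  r1 <- sqrt(rowSums(d1^2))
  a1 <- ifelse(r1 == 0, 0, atan2(d1[, 2L], d1[, 1L]))
  set1 <- as.vector(rbind(r1, a1))
  # set 2: dx[i, j] = p_i.x - m_j.x
  dx <- outer(landmarks[, 1L], mean_shape[, 1L], `-`)
  dy <- outer(landmarks[, 2L], mean_shape[, 2L], `-`)
  r2 <- sqrt(dx^2 + dy^2)
  a2 <- ifelse(r2 == 0, 0, atan2(dy, dx))
  # row-major in i then j, (radius, angle) interleaved per pair
  set2 <- as.vector(rbind(as.vector(t(r2)), as.vector(t(a2))))
  # set 3: pairwise distances i < j lexicographic
  pr <- feature_table[feature_table$set == 3L, c("i", "j")]
  dd <- landmarks[pr$i, , drop = FALSE] - landmarks[pr$j, , drop = FALSE]
  set3 <- sqrt(rowSums(dd^2))

  v <- c(set1, set2, set3)
  names(v) <- feature_table$name
  structure(v, feature_table = feature_table, class = "geom_descriptor")
}

#' @export
print.geom_descriptor <- function(x, ...) {
  ft <- attr(x, "feature_table")
  cat("Geometric descriptor: ", length(x), " features over ",
      max(ft$i, na.rm = TRUE), " landmarks\n", sep = "")
  cat("  kinds:", paste(names(table(ft$kind)), table(ft$kind),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tally of descriptor features per kind
#'
#' Counts radius, angle and distance features, optionally restricted to a
#' logical selection mask over the descriptor entries.
#'
#' @param feature_table A [descriptor_feature_table()] (or a
#'   `geom_descriptor`, whose table is then used).
#' @param mask Optional logical vector selecting features.
#' @return Named integer vector with entries `radius`, `angle`, `distance`.
#' @export
feature_kind_partition <- function(feature_table, mask = NULL) {
  if (inherits(feature_table, "geom_descriptor"))
    feature_table <- attr(feature_table, "feature_table")
  kinds <- feature_table$kind
  if (!is.null(mask)) {
    if (length(mask) != length(kinds)) stop("mask length mismatch")
    kinds <- kinds[mask]
  }
  out <- c(radius = 0L, angle = 0L, distance = 0L)
  tb <- table(kinds)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Geometric descriptors for a set of faces
#'
#' Convenience wrapper: computes the mean shape from (a training subset of)
#' the samples and returns the descriptor matrix for all samples.
#'
#' @param landmark_sets List of P x 2 landmark matrices.
#' @param mean_shape Optional mean shape; computed from `landmark_sets` when
#'   missing (pass the training-fold mean to avoid leakage in CV).
#' @return List with `features` (n x D matrix), `mean_shape`, and
#'   `feature_table`.
#' @export
geometric_descriptor_matrix <- function(landmark_sets, mean_shape = NULL) {
  if (is.null(mean_shape)) mean_shape <- compute_mean_shape(landmark_sets)
  ft <- descriptor_feature_table(nrow(mean_shape))
  X <- t(vapply(landmark_sets,
                function(lm) as.numeric(geometric_descriptor(lm, mean_shape, ft)),
                numeric(nrow(ft))))
  colnames(X) <- ft$name
  list(features = X, mean_shape = mean_shape, feature_table = ft)
}
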
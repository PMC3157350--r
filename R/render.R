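# Deterministic 2-D parametric face renderer: filled polygons/ellipses for
# facial parts on a shaded oval, followed by light Gaussian smoothing.
# Appearance is a pure function of landmarks and the two appearance latents,
# so structural and holistic channels carry shared signal.

# pixel-center grids: X[r, c] = 0-based x of column c, Y[r, c] = 0-based y of row r
pixel_grid <- function(size) {
  list(X = matrix(rep(0:(size - 1L), each = size), size, size),
       Y = matrix(rep(0:(size - 1L), times = size), size, size))
}

in_ellipse <- function(X, Y, cx, cy, a, b) {
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

# even-odd point-in-polygon, vectorized over the grid
in_polygon <- function(X, Y, vx, vy) {
  n <- length(vx)
  inside <- matrix(FALSE, nrow(X), ncol(X))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > Y) != (vy[j] > Y)) &
      (X < (vx[j] - vx[i]) * (Y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from every pixel to segment (p1, p2)
seg_dist <- function(X, Y, p1, p2) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  L2 <- dx^2 + dy^2
  if (L2 == 0) return(sqrt((X - p1[1])^2 + (Y - p1[2])^2))
  t <- pmin(pmax(((X - p1[1]) * dx + (Y - p1[2]) * dy) / L2, 0), 1)
  sqrt((X - (p1[1] + t * dx))^2 + (Y - (p1[2] + t * dy))^2)
}

gaussian_blur <- function(img, sigma = 0.9, radius = 2L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  pad <- function(M) {  # replicate padding
    M <- M[c(rep(1L, radius), 1:n, rep(n, radius)), , drop = FALSE]
    M[, c(rep(1L, radius), 1:m, rep(m, radius)), drop = FALSE]
  }
  Mp <- pad(img)
  out <- matrix(0, n + 2L * radius, m + 2L * radius)
  for (s in (-radius):radius)  # vertical pass
    out[(radius + 1):(radius + n), ] <- out[(radius + 1):(radius + n), ] +
      k[s + radius + 1L] * Mp[(radius + 1 + s):(radius + n + s), ]
  res <- matrix(0, n, m)
  for (s in (-radius):radius)  # horizontal pass
    res <- res + k[s + radius + 1L] *
      out[(radius + 1):(radius + n), (radius + 1 + s):(radius + m + s)]
  res
}

#' Render a face image from its landmarks
#'
#' Draws a shaded skin oval, brows, eyes, nose and mouth as filled primitives
#' positioned by the landmark set, then applies light Gaussian smoothing.
#' The output depends only on the arguments, making appearance a
#' deterministic function of structure plus the two appearance latents.
#'
#' @param landmarks P x 2 landmark matrix with the template rownames.
#' @param size Output side length in pixels.
#' @param skin_tone Base skin intensity in [0, 1].
#' @param brow_shade Brow/feature darkness in [0, 1].
#' @return A `size` x `size` numeric matrix in [0, 1]; `img[r, c]` is the
#'   pixel at 0-based coordinates (x = c-1, y = r-1).
#' @export
render_face <- function(landmarks, size = 64L, skin_tone = 0.72,
                        brow_shade = 0.25) {
  g <- function(nm) landmarks[landmark_index(nm, landmarks), ]
  gr <- pixel_grid(size)
  X <- gr$X; Y <- gr$Y
  img <- matrix(0.15, size, size)

  # skin oval
  top <- min(landmarks[1:4, 2L]) - 7
  cx <- (g("cheek_l")[1] + g("cheek_r")[1]) / 2
  cy <- (top + g("chin")[2]) / 2
  a <- (g("cheek_r")[1] - g("cheek_l")[1]) / 2 + 2.5
  b <- (g("chin")[2] - top) / 2 + 2
  rho2 <- ((X - cx) / a)^2 + ((Y - cy) / b)^2
  face <- rho2 <= 1
  img[face] <- skin_tone * (1 - 0.22 * rho2[face])

  # brows: thickened segments
  for (side in list(c("brow_l_out", "brow_l_in"), c("brow_r_in", "brow_r_out"))) {
    m <- seg_dist(X, Y, g(side[1]), g(side[2])) <= 1.4
    img[m] <- brow_shade
  }
  # eyes: ellipses spanning the corner pairs
  for (side in list(c("eye_l_out", "eye_l_in"), c("eye_r_in", "eye_r_out"))) {
    p1 <- g(side[1]); p2 <- g(side[2])
    ea <- sqrt(sum((p1 - p2)^2)) / 2 + 0.5
    m <- in_ellipse(X, Y, (p1[1] + p2[1]) / 2, (p1[2] + p2[2]) / 2, ea, 0.45 * ea)
    img[m] <- 0.12
  }
  # nose: shadow polygon bridge -> left wing -> tip -> right wing
  np <- rbind(g("nose_bridge"), g("nose_l"), g("nose_tip"), g("nose_r"))
  img[in_polygon(X, Y, np[, 1], np[, 2])] <- skin_tone * 0.78
  # mouth: quad through corners, top and bottom, plus the lip line so the
  # corners remain sharp after smoothing
  mp <- rbind(g("mouth_l"), g("mouth_top"), g("mouth_r"), g("mouth_bottom"))
  img[in_polygon(X, Y, mp[, 1], mp[, 2])] <- 0.35
  img[seg_dist(X, Y, g("mouth_l"), g("mouth_r")) <= 0.9] <- 0.3

  # quantize to the 8-bit levels used on disk, so written PNGs round-trip
  round(pmin(pmax(gaussian_blur(img), 0), 1) * 255) / 255
}
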
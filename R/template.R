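#' The nine social trait dimensions
#'
#' Trait judgments rated on a continuous 1--9 scale in the behavioural data
#' this pipeline emulates.
#'
#' @return Character vector of nine trait names.
#' @export
trait_names <- function() {
  c("attractive", "competent", "trustworthy", "dominant", "mean",
    "frightening", "extroverted", "threatening", "likable")
}

#' Rating scale endpoints
#' @return Numeric length-2 vector `c(low, high)`.
#' @export
rating_range <- function() c(1, 9)

#' 21-point fiducial landmark template
#'
#' The fixed anatomical layout shared by every face: brow ends, eye corners,
#' nose bridge/wings/tip, mouth corners/top/bottom, chin, cheeks and jaw.
#' Coordinates are pixels in an `size x size` image, origin top-left,
#' x rightward, y downward, 0-based.
#'
#' @param size Image side length in pixels (default 64).
#' @return A P x 2 matrix with rownames giving the anatomical labels.
#' @export
face_template <- function(size = 64) {
  pts <- matrix(c(
    18, 22,   # brow_l_out
    26, 21,   # brow_l_in
    38, 21,   # brow_r_in
    46, 22,   # brow_r_out
    19, 27,   # eye_l_out
    26, 27,   # eye_l_in
    38, 27,   # eye_r_in
    45, 27,   # eye_r_out
    32, 28,   # nose_bridge
    28, 38,   # nose_l
    32, 40,   # nose_tip
    36, 38,   # nose_r
    25, 47,   # mouth_l
    32, 45,   # mouth_top
    39, 47,   # mouth_r
    32, 50,   # mouth_bottom
    32, 58,   # chin
    14, 38,   # cheek_l
    50, 38,   # cheek_r
    19, 50,   # jaw_l
    45, 50    # jaw_r
  ), ncol = 2, byrow = TRUE)
  rownames(pts) <- c("brow_l_out", "brow_l_in", "brow_r_in", "brow_r_out",
                     "eye_l_out", "eye_l_in", "eye_r_in", "eye_r_out",
                     "nose_bridge", "nose_l", "nose_tip", "nose_r",
                     "mouth_l", "mouth_top", "mouth_r", "mouth_bottom",
                     "chin", "cheek_l", "cheek_r", "jaw_l", "jaw_r")
  colnames(pts) <- c("x", "y")
  pts * (size / 64)
}

landmark_index <- function(name, landmarks) {
  i <- match(name, rownames(landmarks))
  if (is.na(i)) stop("unknown landmark: ", name)
  i
}
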
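# Colour-transfer working space: RGB -> LMS -> log10 -> decorrelated
# l-alpha-beta, as introduced for statistical colour transfer between
# images. All matrices are the published constants; inverses are computed
# numerically once at load.

.M_RGB2LMS <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444), nrow = 3, byrow = TRUE)

.M_LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), nrow = 3, byrow = TRUE)

.M_LMS2RGB <- solve(.M_RGB2LMS)
.M_LAB2LMS <- solve(.M_LMS2LAB)

# Floor on linear LMS before taking log10; corresponds to a deep black.
.LMS_EPS <- 1e-4

#' Convert 8-bit RGB values to the l-alpha-beta colour-transfer space
#'
#' @param rgb Numeric matrix with 3 columns (R, G, B), values in [0, 255].
#' @return Matrix with 3 columns (l, alpha, beta).
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  lms <- (rgb / 255) %*% t(.M_RGB2LMS)
  lms <- pmax(lms, .LMS_EPS)
  log10(lms) %*% t(.M_LMS2LAB)
}

#' Convert l-alpha-beta values back to 8-bit RGB
#'
#' @param lab Numeric matrix with 3 columns (l, alpha, beta).
#' @return Matrix with 3 columns (R, G, B), clipped to [0, 255].
#' @export
lab_to_rgb <- function(lab) {
  lab <- matrix(as.numeric(lab), ncol = 3)
  lms <- 10^(lab %*% t(.M_LAB2LMS))
  clamp(lms %*% t(.M_LMS2RGB) * 255, 0, 255)
}

# Pixel matrix (N x 3, 0-255) of an RGB array, optionally restricted to a
# logical mask.
pixel_matrix <- function(img, mask = NULL) {
  assert_rgb(img)
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  m
}
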
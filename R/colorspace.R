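#' Auxiliary color spaces: Ruderman l-alpha-beta and HSV hue
#'
#' The color-transfer normalizer and the color-error metrics operate in the
#' Ruderman l-alpha-beta opponent space: RGB is mapped to LMS cone
#' responses, log-transformed (natural log), and decorrelated into a
#' luminance-like channel `l` and two opponent channels. Channel naming
#' follows the convention used throughout this toolkit's metric suite:
#' `alpha` is the red-green opponent `(log L - log M) / sqrt(2)` and `beta`
#' is the yellow-blue opponent `(log L + log M - 2 log S) / sqrt(6)`.
#'
#' @name colorspace
NULL

.rgb2lms <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444), nrow = 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)

# rows: l, alpha (red-green), beta (yellow-blue)
.loglms2lab <- matrix(c(
  1 / sqrt(3),  1 / sqrt(3),  1 / sqrt(3),
  1 / sqrt(2), -1 / sqrt(2),  0,
  1 / sqrt(6),  1 / sqrt(6), -2 / sqrt(6)), nrow = 3, byrow = TRUE)
.lab2loglms <- solve(.loglms2lab)

#' Convert an RGB image to Ruderman l-alpha-beta space
#'
#' @param img RGB image array (0-255).
#' @return height x width x 3 array with channels `(l, alpha, beta)`;
#'   `alpha` is the red-green opponent, `beta` the yellow-blue opponent.
#' @export
rgb_to_lab <- function(img) {
  assert_rgb(img)
  dm <- dim(img)
  lms <- matrix(img, ncol = 3L) %*% t(.rgb2lms) / 255
  lms <- log(pmax(lms, 1e-6))
  lab <- lms %*% t(.loglms2lab)
  array(lab, dim = dm)
}

#' @rdname rgb_to_lab
#' @param lab height x width x 3 l-alpha-beta array.
#' @return `lab_to_rgb()` returns an RGB image array, clamped to `[0, 255]`
#'   with half-up rounding.
#' @export
lab_to_rgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L || anyNA(lab))
    stop_invalid_input("lab must be a height x width x 3 array of finite values")
  dm <- dim(lab)
  lms <- exp(matrix(lab, ncol = 3L) %*% t(.lab2loglms))
  rgb <- lms %*% t(.lms2rgb) * 255
  array(clamp255(round_half_up(rgb)), dim = dm)
}

#' HSV hue channel with chromatic-validity mask
#'
#' Standard hexcone hue in degrees `[0, 360)`. Hue is undefined where
#' saturation is zero (gray pixels); those pixels are assigned hue 0 and
#' flagged `FALSE` in the `chromatic` mask so hue statistics can exclude
#' them rather than absorb an arbitrary value.
#'
#' @param img RGB image array (0-255).
#' @return list with `hue` (height x width matrix, degrees) and
#'   `chromatic` (logical matrix, `TRUE` where hue is defined).
#' @export
rgb_to_hue <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2])
  g <- matrix(img[, , 2], d[1], d[2])
  b <- matrix(img[, , 3], d[1], d[2])
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  ch <- mx - mn
  hue <- matrix(0, nrow(r), ncol(r))
  chromatic <- ch > 0
  i <- chromatic & mx == r
  hue[i] <- ((g[i] - b[i]) / ch[i]) %% 6
  i <- chromatic & mx == g & mx != r
  hue[i] <- (b[i] - r[i]) / ch[i] + 2
  i <- chromatic & mx == b & mx != r & mx != g
  hue[i] <- (r[i] - g[i]) / ch[i] + 4
  hue <- (hue * 60) %% 360
  list(hue = hue, chromatic = chromatic)
}
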
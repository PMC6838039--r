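#' Beer-Lambert optical density transforms and stain deconvolution
#'
#' In brightfield microscopy the transmitted intensity of a stained specimen
#' follows the Beer-Lambert law: `I = I0 * exp(-V %*% S)` where `I0` is the
#' background (unstained) intensity, the columns of `V` are the unit optical
#' density (OD) vectors of the pure stains, and `S` holds per-pixel stain
#' concentrations. Absorbances add linearly in OD space, so converting to
#' `OD = log(I0 / I)` turns stain unmixing into linear algebra.
#'
#' @name stain_model
NULL

check_background <- function(background) {
  if (!is.numeric(background) || !length(background) %in% c(1L, 3L) ||
      anyNA(background) || any(background < 1) || any(background > 255))
    stop_invalid_input("background brightfield intensities must lie in [1, 255]")
  if (length(background) == 1L) background <- rep(background, 3L)
  background
}

#' Convert an RGB image to optical density
#'
#' `od = log(background / clamp(pixel, 1, background))` per channel.
#' Zero-intensity pixels are clamped to 1 before the log so the OD stays
#' finite; pixels brighter than the background are clamped down to it so the
#' OD stays non-negative.
#'
#' @param img RGB image array (values 0-255).
#' @param background per-channel brightfield intensity, length 1 or 3, in
#'   `[1, 255]`. Default 255.
#' @return height x width x 3 array of non-negative optical densities.
#' @export
rgb_to_od <- function(img, background = 255) {
  assert_rgb(img)
  bg <- check_background(background)
  od <- img
  for (c in 1:3) od[, , c] <- log(bg[c] / pmin(pmax(img[, , c], 1), bg[c]))
  od
}

#' Convert optical density back to an RGB image
#'
#' `pixel = round(background * exp(-od))`, clamped to `[0, 255]` with
#' half-up rounding.
#'
#' @param od height x width x 3 array of non-negative optical densities.
#' @inheritParams rgb_to_od
#' @return RGB image array.
#' @export
od_to_rgb <- function(od, background = 255) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L ||
      anyNA(od) || any(!is.finite(od)) || min(od) < 0)
    stop_invalid_input("od must be a height x width x 3 array of finite non-negative values")
  bg <- check_background(background)
  out <- od
  for (c in 1:3) out[, , c] <- clamp255(round_half_up(bg[c] * exp(-od[, , c])))
  out
}

od_flat <- function(od) matrix(od, ncol = 3L)

assert_stain_matrix <- function(V) {
  if (!is.matrix(V) || !all(dim(V) == c(3L, 2L)) || anyNA(V) || min(V) < 0)
    stop_invalid_input("a stain matrix must be 3x2 with non-negative entries")
  norms <- sqrt(colSums(V^2))
  if (any(abs(norms - 1) > 1e-6))
    stop_invalid_input("stain matrix columns must be unit-norm")
  invisible(V)
}

make_stain_matrix <- function(V) {
  V <- V / rep(sqrt(colSums(V^2)), each = 3L)
  dimnames(V) <- list(c("red", "green", "blue"), c("hematoxylin", "eosin"))
  V
}

# Order columns so hematoxylin is the vector with the larger blue OD
# component (ties broken by the larger green component).
order_stain_columns <- function(V) {
  b <- V[3, ]
  pick <- if (abs(b[1] - b[2]) > 1e-12) which.max(b) else which.max(V[2, ])
  make_stain_matrix(V[, c(pick, 3L - pick), drop = FALSE])
}

#' Estimate H&E stain vectors by SVD (Macenko method)
#'
#' Discards near-brightfield pixels (OD vector norm below `od_threshold`),
#' finds the dominant plane of the remaining OD cloud by singular value
#' decomposition, and picks the two stain directions at the extreme
#' percentiles of the in-plane angle distribution. Columns are clamped to
#' non-negative OD, normalized to unit length, and ordered
#' (hematoxylin, eosin) by blue OD component.
#'
#' @param od optical density array from [rgb_to_od()].
#' @param od_threshold foreground OD norm threshold (default 0.15).
#' @param angular_percentile percentile (in percent) for the angular
#'   extremes; default 1 selects the 1st and 99th percentiles.
#' @param min_foreground minimum number of foreground pixels required.
#' @return 3x2 stain matrix, columns `hematoxylin` and `eosin`.
#' @export
estimate_stain_matrix <- function(od, od_threshold = 0.15, angular_percentile = 1,
                                  min_foreground = 20L) {
  if (od_threshold < 0) stop_invalid_input("od_threshold must be non-negative")
  if (angular_percentile <= 0 || angular_percentile >= 50)
    stop_invalid_input("angular_percentile must be in (0, 50)")
  X <- od_flat(od)
  fg <- X[sqrt(rowSums(X^2)) >= od_threshold, , drop = FALSE]
  if (nrow(fg) < min_foreground)
    stop_degenerate_stain(sprintf(
      "too few foreground pixels (%d < %d) for stain estimation", nrow(fg), min_foreground))
  sv <- svd(fg, nu = 0, nv = 2)
  if (sv$d[2] <= 1e-6 * sv$d[1])
    stop_degenerate_stain("OD cloud is rank-deficient (single chromatic direction)")
  basis <- sv$v
  # orient basis vectors toward the data so angles are stable
  for (k in 1:2) if (sum(fg %*% basis[, k]) < 0) basis[, k] <- -basis[, k]
  ang <- atan2(fg %*% basis[, 2], fg %*% basis[, 1])
  q <- stats::quantile(ang, c(angular_percentile, 100 - angular_percentile) / 100,
                       names = FALSE, type = 7)
  v1 <- basis %*% c(cos(q[1]), sin(q[1]))
  v2 <- basis %*% c(cos(q[2]), sin(q[2]))
  V <- cbind(pmax(v1, 0), pmax(v2, 0))
  if (any(colSums(V) == 0))
    stop_degenerate_stain("estimated stain direction collapsed to zero after clamping")
  order_stain_columns(V)
}

#' Unmix an OD image into per-stain concentrations
#'
#' Per-pixel least squares: `S = pinv(V) %*% od`. With a 3x2 stain matrix
#' the system is overdetermined, so the solution is the orthogonal
#' projection of each OD vector onto the stain plane; small negative
#' concentrations can occur and are clipped only on recomposition.
#'
#' @param od optical density array.
#' @param V 3x2 stain matrix.
#' @return height x width x 2 concentration array (hematoxylin, eosin).
#' @export
deconvolve <- function(od, V) {
  assert_stain_matrix(V)
  d <- svd(V, nu = 0, nv = 0)$d
  if (d[2] <= 1e-8 * d[1])
    stop_degenerate_stain("stain matrix is ill-conditioned (near-parallel columns)")
  pinv <- solve(crossprod(V), t(V))       # 2x3
  S <- od_flat(od) %*% t(pinv)            # N x 2
  array(S, dim = c(dim(od)[1:2], 2L))
}

#' Re-render an RGB image from stain concentrations
#'
#' Applies the Beer-Lambert law forward: `od = V %*% max(S, 0)` followed by
#' [od_to_rgb()]. Negative concentrations (least-squares artifacts) are
#' clipped to zero.
#'
#' @param V 3x2 stain matrix.
#' @param S height x width x 2 concentration array.
#' @inheritParams rgb_to_od
#' @return RGB image array.
#' @export
recompose <- function(V, S, background = 255) {
  assert_stain_matrix(V)
  if (!is.array(S) || length(dim(S)) != 3L || dim(S)[3] != 2L)
    stop_invalid_input("S must be a height x width x 2 concentration array")
  od <- pmax(matrix(S, ncol = 2L), 0) %*% t(V)
  od_to_rgb(array(od, dim = c(dim(S)[1:2], 3L)), background)
}

#' Angular error between two stain matrices
#'
#' Per-column angle (in degrees) between corresponding unit stain vectors;
#' the standard yardstick for stain-vector recovery accuracy.
#'
#' @param V,W 3x2 stain matrices.
#' @return length-2 numeric vector of angles in degrees.
#' @export
stain_angle_error <- function(V, W) {
  assert_stain_matrix(V); assert_stain_matrix(W)
  sapply(1:2, function(k) {
    ct <- sum(V[, k] * W[, k]) / (sqrt(sum(V[, k]^2)) * sqrt(sum(W[, k]^2)))
    acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  })
}

#' Serialize / restore a stain matrix as JSON
#'
#' Row-major 3x2 layout with channel and stain labels.
#'
#' @param V 3x2 stain matrix.
#' @param path JSON file path.
#' @export
write_stain_matrix <- function(V, path) {
  assert_stain_matrix(V)
  jsonlite::write_json(list(
    channels = c("red", "green", "blue"),
    stains = c("hematoxylin", "eosin"),
    vectors = lapply(1:3, function(r) unname(V[r, ]))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_matrix
#' @export
read_stain_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vectors
  V <- if (is.matrix(v)) v else do.call(rbind, lapply(v, as.numeric))
  V <- make_stain_matrix(V)
  assert_stain_matrix(V)
  V
}
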
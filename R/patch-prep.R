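#' Patch extraction for nucleus-boundary classifier training
#'
#' Two patching protocols are supported: dense sliding-window patches with
#' a center-pixel label (for patch-classification networks: 51 x 51
#' windows at stride 7 by default) and non-overlapping tiles with one-hot
#' dense labels (for encoder-decoder networks: 256 x 256 by default).
#' Trailing image strips that do not fit a full patch are discarded, a
#' deterministic convention that makes patch counts a closed-form function
#' of the image size. All coordinates are 0-based (row, col) from the
#' top-left.
#'
#' @name patch_prep
NULL

assert_labels <- function(labels, dims) {
  if (!is.matrix(labels) || !all(dim(labels) == dims) ||
      !all(labels %in% 0:2))
    stop_invalid_input("labels must be a matrix over {0,1,2} aligned with the image")
  invisible(labels)
}

#' Extract center-labeled sliding-window patches
#'
#' Origins lie on the grid `(i*stride, j*stride)` (0-based) for every
#' position where the full patch fits; the patch label is the ternary
#' class of its center pixel. The patch count per axis is
#' `floor((dim - size)/stride) + 1`.
#'
#' @param img RGB image array.
#' @param labels ternary label matrix over `{0,1,2}` aligned with `img`.
#' @param size odd patch side (default 51).
#' @param stride grid stride in pixels (default 7).
#' @param materialize if `FALSE`, return only the manifest (origins and
#'   center labels) without pixel crops — useful for counting and for
#'   deferred extraction on large images.
#' @return list with `manifest` (data.frame: patch_id, origin_row,
#'   origin_col, center_label) and, when materialized, `patches` (list of
#'   lists with `pixels`, `center_label`, `origin`).
#' @export
extract_center_patches <- function(img, labels, size = 51L, stride = 7L,
                                   materialize = TRUE) {
  assert_rgb(img)
  d <- dim(img)
  assert_labels(labels, d[1:2])
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1 || stride < 1) stop_invalid_input("size and stride must be >= 1")
  if (size %% 2L == 0L) stop_invalid_input("size must be odd (a unique center pixel)")
  if (d[1] < size || d[2] < size)
    stop_invalid_input("image is smaller than the patch size")
  half <- (size - 1L) %/% 2L
  orows <- seq(0L, d[1] - size, by = stride)
  ocols <- seq(0L, d[2] - size, by = stride)
  grid <- expand.grid(origin_col = ocols, origin_row = orows)[, 2:1]
  center_label <- labels[cbind(grid$origin_row + half + 1L,
                               grid$origin_col + half + 1L)]
  manifest <- data.frame(patch_id = sprintf("p%06d", seq_len(nrow(grid))),
                         origin_row = grid$origin_row,
                         origin_col = grid$origin_col,
                         center_label = as.integer(center_label),
                         stringsAsFactors = FALSE)
  out <- list(manifest = manifest, size = size, stride = stride)
  if (materialize) {
    out$patches <- lapply(seq_len(nrow(manifest)), function(i) {
      r <- manifest$origin_row[i]; c <- manifest$origin_col[i]
      list(pixels = img[r + seq_len(size), c + seq_len(size), , drop = FALSE],
           center_label = manifest$center_label[i],
           origin = c(r, c))
    })
  }
  out
}

one_hot <- function(labels) {
  oh <- array(0, dim = c(dim(labels), 3L))
  for (k in 0:2) oh[, , k + 1L] <- (labels == k) * 1
  oh
}

#' Extract non-overlapping dense-label tiles
#'
#' Tiles the image from the top-left on a `size`-pixel grid; trailing
#' partial strips are discarded. Each tile carries a one-hot
#' (background, boundary, nuclei) label array.
#'
#' @inheritParams extract_center_patches
#' @param size tile side (default 256).
#' @return list with `manifest` and, when materialized, `patches` (lists
#'   with `pixels`, `labels_onehot`, `origin`).
#' @export
extract_dense_patches <- function(img, labels, size = 256L, materialize = TRUE) {
  assert_rgb(img)
  d <- dim(img)
  assert_labels(labels, d[1:2])
  size <- as.integer(size)
  if (size < 1) stop_invalid_input("size must be >= 1")
  if (d[1] < size || d[2] < size)
    stop_invalid_input("image is smaller than the patch size")
  orows <- seq(0L, d[1] - size, by = size)
  ocols <- seq(0L, d[2] - size, by = size)
  grid <- expand.grid(origin_col = ocols, origin_row = orows)[, 2:1]
  manifest <- data.frame(patch_id = sprintf("p%06d", seq_len(nrow(grid))),
                         origin_row = grid$origin_row,
                         origin_col = grid$origin_col,
                         stringsAsFactors = FALSE)
  out <- list(manifest = manifest, size = size)
  if (materialize) {
    out$patches <- lapply(seq_len(nrow(manifest)), function(i) {
      r <- manifest$origin_row[i]; c <- manifest$origin_col[i]
      list(pixels = img[r + seq_len(size), c + seq_len(size), , drop = FALSE],
           labels_onehot = one_hot(labels[r + seq_len(size), c + seq_len(size)]),
           origin = c(r, c))
    })
  }
  out
}

#' Closed-form patch counts
#'
#' @param h,w image height and width.
#' @inheritParams extract_center_patches
#' @return integer patch count.
#' @export
count_center_patches <- function(h, w, size = 51L, stride = 7L) {
  if (h < size || w < size) return(0L)
  as.integer(((h - size) %/% stride + 1L) * ((w - size) %/% stride + 1L))
}

#' @rdname count_center_patches
#' @export
count_dense_patches <- function(h, w, size = 256L) {
  as.integer((h %/% size) * (w %/% size))
}

# 90-degree rotation: pixel (r, c) -> (c, H-1-r) in 0-based coordinates.
rot90_matrix <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rot90_array <- function(a) {
  d <- dim(a)
  out <- array(0, dim = c(d[2], d[1], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- rot90_matrix(a[, , k])
  out
}

#' Right-angle rotation augmentation
#'
#' Returns the patch plus its 90, 180 and 270 degree rotations, with
#' labels rotated identically; the center label of a center-labeled patch
#' is invariant (the center is a fixed point of the rotation group).
#'
#' @param patch a single patch as returned by [extract_center_patches()]
#'   or [extract_dense_patches()] (elements of `$patches`).
#' @return list of 4 patches.
#' @export
augment_rotations <- function(patch) {
  px <- patch$pixels
  if (is.null(px) || dim(px)[1] != dim(px)[2])
    stop_invalid_input("rotation augmentation requires a square patch")
  out <- vector("list", 4L)
  out[[1]] <- patch
  cur <- patch
  for (i in 2:4) {
    cur$pixels <- rot90_array(cur$pixels)
    if (!is.null(cur$labels_onehot)) cur$labels_onehot <- rot90_array(cur$labels_onehot)
    out[[i]] <- cur
  }
  out
}

#' Recombine tiled probability maps onto a canvas
#'
#' Pastes per-tile ternary probability maps (or one-hot label tiles) back
#' by their origins. Canvas pixels not covered by any tile are filled with
#' background probability 1 and flagged in the `covered` attribute.
#'
#' @param patches list of lists with `origin` (0-based row, col) and
#'   either a `probs` or `labels_onehot` height x width x 3 array.
#' @param canvas_shape integer c(height, width).
#' @return ternary probability map with logical attribute `covered`.
#' @export
recombine <- function(patches, canvas_shape) {
  if (length(patches) == 0) stop_invalid_input("patches must be non-empty")
  H <- canvas_shape[1]; W <- canvas_shape[2]
  canvas <- array(0, dim = c(H, W, 3L))
  canvas[, , 1] <- 1
  covered <- matrix(FALSE, H, W)
  for (p in patches) {
    a <- if (!is.null(p$probs)) p$probs else p$labels_onehot
    if (is.null(a)) stop_invalid_input("each patch needs a probs or labels_onehot array")
    r <- p$origin[1]; c <- p$origin[2]
    dh <- dim(a)[1]; dw <- dim(a)[2]
    if (r < 0 || c < 0 || r + dh > H || c + dw > W)
      stop_invalid_input("patch extends beyond the canvas")
    if (any(covered[r + seq_len(dh), c + seq_len(dw)]))
      stop_invalid_input("overlapping patch origins")
    canvas[r + seq_len(dh), c + seq_len(dw), ] <- a
    covered[r + seq_len(dh), c + seq_len(dw)] <- TRUE
  }
  attr(canvas, "covered") <- covered
  canvas
}

#' Write a patch manifest CSV
#'
#' @param extraction result of [extract_center_patches()] or
#'   [extract_dense_patches()].
#' @param path CSV path.
#' @param source_image identifier recorded in the manifest.
#' @export
write_patch_manifest <- function(extraction, path, source_image = "") {
  man <- extraction$manifest
  man <- cbind(source_image = source_image, man)
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
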
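#' Ternary probability maps: ensembling, binarization, post-processing
#'
#' Nucleus-boundary segmentation models emit three-channel probability maps
#' over (background, boundary, nuclei). Maps from models trained on
#' differently normalized data are fused by plain per-pixel averaging, so
#' regions where the models agree are reinforced and disagreements are
#' attenuated. The fused nuclei channel is binarized (Otsu or fixed
#' threshold) and cleaned by a morphological chain.
#'
#' Probability maps are height x width x 3 arrays in `[0, 1]`, channels
#' ordered (background, boundary, nuclei). Channels need not sum to one
#' (sigmoid-style outputs are allowed).
#'
#' @name segmentation_post
NULL

CLASS_BACKGROUND <- 0L
CLASS_BOUNDARY <- 1L
CLASS_NUCLEI <- 2L

assert_prob_map <- function(p, what = "probability map") {
  if (!is.array(p) || length(dim(p)) != 3L || dim(p)[3] != 3L ||
      anyNA(p) || min(p) < 0 || max(p) > 1)
    stop_invalid_input(sprintf(
      "%s must be a height x width x 3 array with values in [0, 1]", what))
  invisible(p)
}

#' Hard class labels from a ternary probability map
#'
#' Per-pixel argmax over the three channels; ties are broken toward the
#' lower class index (background < boundary < nuclei), a conservative rule
#' that prefers not to call a nucleus.
#'
#' @param p ternary probability map.
#' @return height x width integer matrix over `{0, 1, 2}`.
#' @export
argmax_classes <- function(p) {
  assert_prob_map(p)
  m <- matrix(p, ncol = 3L)
  matrix(max.col(m, ties.method = "first") - 1L, dim(p)[1], dim(p)[2])
}

#' Average an ensemble of probability maps
#'
#' `E = (1/N) * sum(P_n)`, channel-wise; the fused map carries the source
#' tag `"ENSEMBLE"`.
#'
#' @param maps non-empty list of ternary probability maps with identical
#'   dimensions.
#' @return ternary probability map.
#' @export
ensemble <- function(maps) {
  if (!is.list(maps) || length(maps) == 0)
    stop_invalid_input("maps must be a non-empty list of probability maps")
  for (p in maps) assert_prob_map(p)
  d <- dim(maps[[1]])
  for (p in maps) if (!all(dim(p) == d))
    stop_invalid_input("all probability maps must have identical dimensions")
  out <- Reduce(`+`, maps) / length(maps)
  attr(out, "source_tag") <- "ENSEMBLE"
  out
}

#' Binarize the nuclei channel of a probability map
#'
#' `method = "otsu"` thresholds the nuclei channel at the value maximizing
#' between-class variance of its 256-bin histogram (pixels strictly above
#' the threshold are foreground); `method = "fixed"` uses `channel >=
#' threshold`. Otsu on a constant channel falls back to the fixed 0.5
#' threshold with a warning.
#'
#' @param p ternary probability map, or a plain matrix treated as the
#'   nuclei channel.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold in `(0, 1)` (default 0.5).
#' @return logical height x width nuclei mask.
#' @export
binarize <- function(p, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  ch <- if (is.matrix(p)) p else { assert_prob_map(p); p[, , 3] }
  if (anyNA(ch) || min(ch) < 0 || max(ch) > 1)
    stop_invalid_input("nuclei channel values must lie in [0, 1]")
  if (method == "fixed") {
    if (threshold <= 0 || threshold >= 1)
      stop_invalid_input("fixed threshold must lie in (0, 1)")
    return(ch >= threshold)
  }
  if (max(ch) - min(ch) < 1e-12) {
    warning("constant nuclei channel: Otsu undefined, using fixed threshold 0.5")
    return(ch >= 0.5)
  }
  thr <- EBImage::otsu(EBImage::Image(ch), range = c(0, 1), levels = 256L)
  ch > thr
}

# 3x3 binary median filter (majority of the 9-pixel neighborhood,
# zero-padded at the borders), implemented by shift-and-sum.
median3 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask * 1L
  acc <- matrix(0L, H, W)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + pad[(1:H) + dr, (1:W) + dc]
  acc >= 5L
}

shift_logical <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Fill enclosed holes: background pixels not 4-connected to the image
# border become foreground.
fill_holes <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    grown <- reach |
      (shift_logical(reach, 1, 0) & bg) | (shift_logical(reach, -1, 0) & bg) |
      (shift_logical(reach, 0, 1) & bg) | (shift_logical(reach, 0, -1) & bg)
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Label connected foreground components (8-connectivity)
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels, 0 for background.
#' @export
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  pos <- matrix(NA_integer_, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    a <- pos
    b <- shift_logical_int(pos, -off[1], -off[2])
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  memb <- if (is.null(edges)) seq_along(idx)
  else igraph::components(igraph::make_graph(as.vector(t(edges)), n = length(idx),
                                             directed = FALSE))$membership
  lab[idx] <- as.integer(memb)
  lab
}

# integer shift with NA padding (companion to shift_logical)
shift_logical_int <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_integer_, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

remove_small_objects <- function(mask, min_px) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Morphological post-processing of a nuclei mask
#'
#' Cleans a binary nuclei prediction with a four-step chain: (1) 3x3
#' binary median filter (removes isolated false positives); (2)
#' morphological closing with a disk structuring element of radius
#' `se_radius`; (3) filling of enclosed holes (background regions not
#' 4-connected to the image border); (4) removal of 8-connected
#' components smaller than `min_object_px`.
#'
#' A single pass of a median filter over a curved object boundary is not
#' a fixed point (convex corners keep eroding), so the chain is iterated
#' until the mask is stable (a handful of passes in practice, capped at
#' `max_iter`). This makes the operation idempotent and guarantees the
#' postconditions: no enclosed holes and no undersized components.
#'
#' @param mask logical nuclei mask.
#' @param min_object_px minimum surviving component area in pixels
#'   (default 30, sized for nuclei at roughly 40x magnification).
#' @param se_radius disk radius of the closing structuring element
#'   (default 2).
#' @param max_iter iteration cap for the stabilizing loop.
#' @return logical mask.
#' @export
postprocess <- function(mask, min_object_px = 30L, se_radius = 2L,
                        max_iter = 25L) {
  if (!is.matrix(mask)) stop_invalid_input("mask must be a logical matrix")
  out <- mask > 0
  brush <- if (se_radius > 0)
    EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  for (i in seq_len(max_iter)) {
    prev <- out
    out <- median3(out)
    if (!is.null(brush)) {
      out <- EBImage::closing(EBImage::Image(out * 1), brush) > 0.5
      out <- matrix(as.logical(out), nrow(mask), ncol(mask))
    }
    out <- fill_holes(out)
    out <- remove_small_objects(out, min_object_px)
    if (identical(out, prev)) return(out)
  }
  warning("postprocess did not reach a fixed point within max_iter passes")
  out
}

#' Test a mask for enclosed holes
#'
#' A hole is a background component with no 4-connected path to the image
#' border.
#'
#' @param mask logical matrix.
#' @return `TRUE` if at least one enclosed hole exists.
#' @export
has_holes <- function(mask) {
  !identical(fill_holes(mask), mask | FALSE)
}

#' Read / write probability maps and masks
#'
#' Probability maps are stored as 32-bit multi-channel TIFF; binary masks
#' as 8-bit PNG with values `{0, 255}`.
#'
#' @param p ternary probability map.
#' @param path output path.
#' @export
write_prob_map <- function(p, path) {
  assert_prob_map(p)
  tiff::writeTIFF(p, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_prob_map
#' @export
read_prob_map <- function(path) {
  p <- tiff::readTIFF(path)
  assert_prob_map(p)
  p
}

#' @rdname write_prob_map
#' @param mask logical mask.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' @rdname write_prob_map
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
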
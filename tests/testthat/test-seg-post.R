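test_that("argmax labeling breaks ties toward the lower class index", {
  p <- array(0, c(1, 1, 3))
  p[1, 1, ] <- c(0.1, 0.2, 0.7)
  expect_equal(argmax_classes(p)[1, 1], 2L)
  p[1, 1, ] <- c(0.4, 0.4, 0.2)
  expect_equal(argmax_classes(p)[1, 1], 0L)
  # exhaustive grid at 0.1 resolution against a brute-force scan
  g <- seq(0, 1, by = 0.1)
  grid <- expand.grid(a = g, b = g, c = g)
  p <- array(0, c(nrow(grid), 1, 3))
  p[, 1, 1] <- grid$a; p[, 1, 2] <- grid$b; p[, 1, 3] <- grid$c
  got <- argmax_classes(p)[, 1]
  ref <- apply(as.matrix(grid), 1, function(r) which(r == max(r))[1] - 1L)
  expect_equal(got, as.integer(ref))
})

test_that("ensemble averaging is exact, idempotent and order-invariant", {
  m <- random_prob_map(seed = 1)
  expect_equal(ensemble(list(m, m, m)), m, ignore_attr = TRUE)
  maps <- lapply(1:6, function(s) random_prob_map(seed = s))
  e <- ensemble(maps)
  # naive per-pixel loop oracle on a subgrid
  for (i in c(1, 7, 16)) for (j in c(2, 9)) for (k in 1:3) {
    v <- 0
    for (n in 1:6) v <- v + maps[[n]][i, j, k]
    expect_equal(e[i, j, k], v / 6, tolerance = 1e-12)
  }
  expect_equal(ensemble(rev(maps)), e, ignore_attr = TRUE)
  expect_identical(attr(e, "source_tag"), "ENSEMBLE")
  expect_error(ensemble(list()), class = "he_invalid_input")
  expect_error(ensemble(list(m, random_prob_map(8, 8))), class = "he_invalid_input")
})

test_that("binarization follows the stated threshold conventions", {
  p <- array(0.9, c(4, 4, 3))
  expect_true(all(binarize(p, "fixed", 0.5)))
  p[, , 3] <- 0.5
  expect_true(all(binarize(p, "fixed", 0.5)))  # >= convention at the threshold
  # bimodal channel: otsu separates the modes exactly
  ch <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  m <- binarize(ch, "otsu")
  expect_equal(m, ch > 0.5)
  # the returned threshold attains (essentially) the maximal between-class
  # variance, checked by exhaustive search over all split points
  set.seed(2)
  ch <- matrix(runif(400)^2, 20, 20)
  got_thr <- EBImage::otsu(EBImage::Image(ch), range = c(0, 1), levels = 256)
  bcv <- function(t) {
    lo <- ch[ch <= t]; hi <- ch[ch > t]
    if (!length(lo) || !length(hi)) return(0)
    length(lo) * length(hi) / length(ch)^2 * (mean(hi) - mean(lo))^2
  }
  best <- max(vapply((0:255) / 255, bcv, 0))
  expect_gte(bcv(got_thr), 0.995 * best)
  expect_warning(binarize(matrix(0.7, 4, 4), "otsu"), "constant")
  # fixed-threshold monotonicity: raising t never adds pixels
  p <- random_prob_map(12, 12, seed = 3)
  for (t in c(0.2, 0.5, 0.8)) {
    m_lo <- binarize(p, "fixed", t)
    m_hi <- binarize(p, "fixed", min(t + 0.2, 0.99))
    expect_true(all(m_lo | !m_hi))
  }
})

test_that("post-processing removes specks, fills holes and drops undersized objects", {
  # single isolated pixel: removed by the median step
  m <- matrix(FALSE, 15, 15); m[8, 8] <- TRUE
  expect_false(any(postprocess(m, min_object_px = 1L)))

  # ring becomes a solid disk
  rr <- row(matrix(0, 31, 31)) - 16; cc <- col(matrix(0, 31, 31)) - 16
  d <- sqrt(rr^2 + cc^2)
  ring <- d >= 5 & d <= 8
  out <- postprocess(ring, min_object_px = 10L)
  expect_false(has_holes(out))
  expect_true(all(out[d <= 5]))

  # component sizes {10, 29, 31}: exactly one survives at min 30
  sizes <- function(x) { l <- label_components(x); if (max(l) == 0) integer() else tabulate(l[l > 0]) }
  comp <- matrix(FALSE, 40, 60)
  comp[2:6, 2:3] <- TRUE                              # 10 px
  comp[20:24, 20:25] <- TRUE; comp[20, 20] <- FALSE   # 29 px
  comp[30:34, 40:46] <- TRUE; comp[30:33, 40] <- FALSE  # 31 px
  expect_equal(sort(sizes(comp)), c(10, 29, 31))
  out <- hestain:::remove_small_objects(comp, 30)
  expect_equal(sizes(out), 31)
})

test_that("component labeling is 8-connective and hole detection 4-connective", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(label_components(m)), 1L)  # diagonal touch joins
  # a diagonal gap does not let a hole escape (4-connectivity for holes)
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  ring[2, 2] <- FALSE  # corner gap: hole still enclosed under 4-connectivity
  expect_true(has_holes(ring))
})

test_that("post-processing is idempotent on simulated prediction masks", {
  for (s in 1:15) {
    sc <- small_scene(seed = 300 + s)
    m <- binarize(simulate_predictor(sc, flip_prob = 0.15, seed = s), "fixed", 0.5)
    pp <- postprocess(m)
    expect_identical(postprocess(pp), pp)
    expect_false(has_holes(pp))
    l <- label_components(pp)
    if (max(l) > 0) expect_gte(min(tabulate(l[l > 0])), 30)
  }
})

test_that("probability maps and masks survive disk round trips", {
  p <- random_prob_map(seed = 9)
  tp <- withr::local_tempfile(fileext = ".tif")
  write_prob_map(p, tp)
  expect_equal(read_prob_map(tp), p, tolerance = 1e-6)
  m <- random_mask(seed = 9)
  mp <- withr::local_tempfile(fileext = ".png")
  write_mask(m, mp)
  expect_equal(read_mask(mp), m)
})
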
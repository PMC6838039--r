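ref_scene_img <- function(seed = 21) render_scene(small_scene(seed = seed, h = 128L, w = 128L, n = 8L))

test_that("fit_reference rejects degenerate references and is deterministic", {
  expect_error(fit_reference(uniform_rgb(c(120, 120, 120), 16, 16), "rh"),
               class = "he_degenerate_reference")
  expect_error(fit_reference(uniform_rgb(c(255, 255, 255), 32, 32), "mc"),
               class = "he_degenerate_stain")
  ref <- ref_scene_img()
  expect_identical(fit_reference(ref, "mc"), fit_reference(ref, "mc"))
})

test_that("reference stain matrix recovered from a rendered reference is accurate", {
  sc <- small_scene(seed = 21, h = 128L, w = 128L, n = 8L)
  mod <- fit_reference(render_scene(sc), "mc")
  expect_lt(max(stain_angle_error(mod$params$stain_matrix, sc$stain_matrix)), 5)
})

test_that("histogram specification matches reference channel CDFs and is a pure LUT", {
  ref <- ref_scene_img(21)
  q <- ref_scene_img(22)
  mod <- fit_reference(ref, "hs")
  out <- normalize_hs(q, mod)
  # output channel quantiles track the reference's
  for (c in 1:3) {
    qs <- quantile(out[, , c], c(.1, .5, .9))
    rs <- quantile(ref[, , c], c(.1, .5, .9))
    expect_lte(max(abs(qs - rs)), 2)
  }
  # self-specification is the identity on present levels
  expect_lte(max(abs(normalize_hs(ref, mod) - ref)), 1)
  # constant reference collapses each channel
  cmod <- fit_reference(uniform_rgb(c(40, 90, 200), 16, 16), "hs")
  cout <- normalize_hs(q, cmod)
  for (c in 1:3) expect_equal(length(unique(as.vector(cout[, , c]))), 1L)
  # images with identical histograms map to identical outputs
  set.seed(5)
  perm <- sample(128 * 128)
  q2 <- q
  for (c in 1:3) q2[, , c] <- matrix(as.vector(q[, , c])[perm], 128, 128)
  o1 <- normalize_hs(q, mod); o2 <- normalize_hs(q2, mod)
  for (c in 1:3) expect_equal(sort(as.vector(o1[, , c])), sort(as.vector(o2[, , c])))
})

test_that("Reinhard transfer imposes the reference moments in l-alpha-beta", {
  ref <- ref_scene_img(21)
  q <- ref_scene_img(23)
  mod <- fit_reference(ref, "rh")
  out <- normalize_rh(q, mod)
  lab <- rgb_to_lab(out)
  rng <- apply(rgb_to_lab(ref), 3, function(x) diff(range(x)))
  for (c in 1:3)
    expect_lt(abs(mean(lab[, , c]) - mod$params$lab_mean[c]), 0.005 * max(rng[c], 1e-3) + 0.005)
  expect_lte(mean(abs(normalize_rh(ref, mod) - ref)), 2)
})

test_that("Macenko normalization is a fixed point for in-model queries and scale-invariant", {
  sc <- small_scene(seed = 21, h = 128L, w = 128L, n = 8L)
  ref <- render_scene(sc)
  mod <- fit_reference(ref, "mc")
  expect_lte(mean(abs(normalize_mc(ref, mod) - ref)), 3)

  # a query differing only by a global per-stain concentration scale maps
  # to (nearly) the same output
  sc2 <- small_scene(seed = 33, h = 128L, w = 128L, n = 8L)
  sc3 <- sc2
  sc3$concentrations <- sc3$concentrations * 0.8
  o2 <- normalize_mc(render_scene(sc2), mod)
  o3 <- normalize_mc(render_scene(sc3), mod)
  expect_lte(mean(abs(o2 - o3)), 2)

  expect_error(normalize_mc(uniform_rgb(c(255, 255, 255), 64, 64), mod),
               class = "he_degenerate_stain")
})

test_that("quantile-mapping normalization imposes reference stain-channel quantiles", {
  sc <- small_scene(seed = 21, h = 128L, w = 128L, n = 8L)
  ref <- render_scene(sc)
  mod <- fit_reference(ref, "kh")
  expect_lte(mean(abs(normalize_kh(ref, mod) - ref)), 3)

  q <- ref_scene_img(34)
  out <- normalize_kh(q, mod)
  Sout <- deconvolve(rgb_to_od(out), mod$params$stain_matrix)
  Sref <- deconvolve(rgb_to_od(ref), mod$params$stain_matrix)
  for (k in 1:2) {
    qo <- quantile(Sout[, , k], c(.05, .25, .5, .75, .95))
    qr <- quantile(Sref[, , k], c(.05, .25, .5, .75, .95))
    expect_lte(max(abs(qo - qr)), 0.02 * diff(range(Sref[, , k])) + 0.02)
  }

  # monotonicity: pixel ordering by hematoxylin concentration is preserved
  Vq <- estimate_stain_matrix(rgb_to_od(q))
  Sq <- matrix(deconvolve(rgb_to_od(q), Vq), ncol = 2)
  p <- (rank(Sq[, 1], ties.method = "average") - 0.5) / nrow(Sq)
  mapped <- approx(mod$params$probs, mod$params$conc_quantiles[, 1], xout = p, rule = 2)$y
  expect_true(all(diff(mapped[order(Sq[, 1])]) >= -1e-12))
})

test_that("normalizers are deterministic and produce valid 8-bit images", {
  ref <- ref_scene_img(21)
  q <- ref_scene_img(25)
  for (m in c("hs", "rh", "mc", "kh")) {
    mod <- fit_reference(ref, m)
    o1 <- normalize_image(q, mod)
    o2 <- normalize_image(q, mod)
    expect_identical(o1, o2)
    expect_true(all(o1 >= 0 & o1 <= 255))
    expect_true(all(o1 == round(o1)))
  }
})

test_that("reference models survive a JSON round trip", {
  ref <- ref_scene_img(21)
  for (m in c("hs", "rh", "mc", "kh")) {
    mod <- fit_reference(ref, m)
    path <- withr::local_tempfile(fileext = ".json")
    write_reference_model(mod, path)
    mod2 <- read_reference_model(path)
    q <- ref_scene_img(26)
    expect_equal(normalize_image(q, mod2), normalize_image(q, mod))
  }
})
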
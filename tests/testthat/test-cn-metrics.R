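# Brute-force oracles, kept deliberately naive and independent of the
# implementation's vectorized paths.
naive_window_grid <- function(x, w) {
  nr <- nrow(x) %/% w; nc <- ncol(x) %/% w
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[[length(out) + 1]] <- x[((i - 1) * w + 1):(i * w), ((j - 1) * w + 1):(j * w)]
  out
}

naive_nmi <- function(img) {
  a <- c()
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2]))
    a <- c(a, mean(img[i, j, ]))
  median(a) / quantile(a, 0.95, names = FALSE)
}

test_that("NMI equals its definition and handles edge cases", {
  expect_equal(nmi(uniform_rgb(c(37, 120, 200))), 1)
  # A(i) exactly {1,...,100}
  vals <- 1:100
  img <- array(rep(vals, 3), c(10, 10, 3))
  expect_equal(nmi(as_rgb_image(img)), median(vals) / quantile(vals, .95, names = FALSE))
  expect_equal(nmi(as_rgb_image(img)), 50.5 / 95.05, tolerance = 1e-12)
  expect_error(nmi(uniform_rgb(c(0, 0, 0))), class = "he_undefined_metric")
  for (s in 1:5) {
    x <- random_rgb(8, 8, seed = s)
    expect_equal(nmi(x), naive_nmi(x), tolerance = 1e-12)
  }
})

test_that("NMH uses chromatic pixels only and linear-interpolation order statistics", {
  expect_equal(nmh(uniform_rgb(c(0, 0, 255))), 1)
  expect_equal(nmh(uniform_rgb(c(10, 200, 30))), 1)
  expect_error(nmh(uniform_rgb(c(128, 128, 128))), class = "he_undefined_metric")
  # half the pixels at hue 100, half at hue 200 -> 150 / 200 = 0.75
  img <- array(0, c(8, 8, 3))
  img[1:4, , 1] <- 85; img[1:4, , 2] <- 255; img[1:4, , 3] <- 0     # hue 100
  img[5:8, , 1] <- 0; img[5:8, , 2] <- 170; img[5:8, , 3] <- 255    # hue 200
  img <- as_rgb_image(img)
  hv <- rgb_to_hue(img)
  expect_equal(sort(unique(as.vector(hv$hue))), c(100, 200))
  expect_equal(nmh(img), 150 / 200, tolerance = 1e-12)
  # gray pixels are excluded, not absorbed as hue 0
  img2 <- img
  img2[1:2, 1:2, ] <- 128
  vals <- c(rep(100, 28), rep(200, 32))
  expect_equal(nmh(img2), median(vals) / quantile(vals, .95, names = FALSE))
})

test_that("AMCE matches a naive double loop and its algebraic identities", {
  a <- random_rgb(24, 24, seed = 1)
  b <- random_rgb(24, 24, seed = 2)
  expect_equal(unname(amce(list(a, b), list(a, b), window_size = 8)), c(0, 0))

  # constant alpha shift of +c appears exactly as amce_alpha = c
  lab <- rgb_to_lab(a)
  got <- amce(list(a), list(a), window_size = 8)
  expect_equal(unname(got), c(0, 0))

  # naive re-implementation on a random pair
  naive_amce <- function(t_list, p_list, w, chan) {
    pool <- function(lst) unlist(lapply(lst, function(im)
      sapply(naive_window_grid(rgb_to_lab(im)[, , chan], w), mean)))
    abs(mean(pool(t_list)) - mean(pool(p_list)))
  }
  got <- amce(list(a), list(b), window_size = 8)
  expect_equal(unname(got[1]), naive_amce(list(a), list(b), 8, 2), tolerance = 1e-12)
  expect_equal(unname(got[2]), naive_amce(list(a), list(b), 8, 3), tolerance = 1e-12)
  # symmetry under set swap
  expect_equal(amce(list(a), list(b), 8), amce(list(b), list(a), 8), tolerance = 1e-12)
  expect_error(amce(list(), list(a)), class = "he_invalid_input")
})

test_that("contrast difference is anti-symmetric and reacts to contrast stretching", {
  a <- random_rgb(32, 32, seed = 3)
  expect_equal(cd(a, a, window_size = 8), 0)
  expect_equal(cd(a, random_rgb(32, 32, seed = 4), 8),
               -cd(random_rgb(32, 32, seed = 4), a, 8), tolerance = 1e-12)
  # affine expansion about the mean increases sd at fixed mean
  set.seed(9)
  base <- array(runif(32 * 32 * 3, 100, 156), c(32, 32, 3))
  stretched <- (base - mean(base)) * 1.3 + mean(base)
  expect_gt(cd(as_rgb_image(round(stretched)), as_rgb_image(round(base)), 8), 0)
  # constant "normalized" image loses all contrast
  expect_lte(cd(uniform_rgb(c(100, 100, 100), 32, 32), a, 8), 0)
  expect_error(cd(a, random_rgb(16, 16, seed = 1), 8), class = "he_invalid_input")

  # naive oracle
  naive_cd <- function(n, u, w) {
    g <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    wn <- naive_window_grid(g(n), w); wu <- naive_window_grid(g(u), w)
    mn <- sapply(wn, mean); mu <- sapply(wu, mean)
    keep <- mn > 0 & mu > 0
    mean(sapply(wn, sd)[keep] / mn[keep]) - mean(sapply(wu, sd)[keep] / mu[keep])
  }
  b <- random_rgb(32, 32, seed = 5)
  expect_equal(cd(a, b, 8), naive_cd(a, b, 8), tolerance = 1e-12)
})

test_that("population report aggregates with sample-sd CV and records missing metrics", {
  imgs <- replicate(4, uniform_rgb(c(30, 80, 190), 16, 16), simplify = FALSE)
  rep <- population_report(imgs)
  expect_equal(rep$summary$cv[rep$summary$metric == "nmi"], 0)
  expect_equal(rep$summary$cv[rep$summary$metric == "nmh"], 0)

  # CV formula: {2,4,6} -> mean 4, sample sd 2, cv 0.5
  expect_equal(sd(c(2, 4, 6)) / mean(c(2, 4, 6)), 0.5)

  imgs <- lapply(1:5, function(s) random_rgb(16, 16, seed = s))
  imgs[[3]] <- uniform_rgb(c(120, 120, 120), 16, 16)  # NMH undefined
  rep <- population_report(imgs, paired_unnormalized = imgs, window_size = 8)
  snmh <- rep$summary[rep$summary$metric == "nmh", ]
  expect_equal(snmh$n_missing, 1)
  expect_equal(snmh$n, 4)
  # brute-force CV recomputation from the per-image table
  for (m in c("nmi", "nmh", "cd")) {
    x <- rep$per_image[[m]]; x <- x[!is.na(x)]
    expect_equal(rep$summary$cv[rep$summary$metric == m], sd(x) / mean(x), tolerance = 1e-12)
  }
  # deterministic ordering by image id
  rep2 <- population_report(imgs[5:1], image_ids = sprintf("img_%03d", 5:1),
                            paired_unnormalized = imgs[5:1], window_size = 8)
  expect_equal(rep2$per_image$nmi, rep$per_image$nmi)
})

test_that("reports are written as CSV with footer rows and a JSON mirror", {
  imgs <- lapply(1:3, function(s) random_rgb(16, 16, seed = s))
  rep <- population_report(imgs, window_size = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, csv, js)
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(tail(tab$image_id, 3), c("mean", "sd", "cv"))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$per_image), 3)
})
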
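#' Color-normalization quality metrics
#'
#' Per-image color-constancy statistics and their population aggregation:
#'
#' * NMI, normalized median intensity: median of the per-pixel channel-mean
#'   intensity divided by its 95th percentile.
#' * NMH, normalized median hue: the same ratio computed on the HSV hue
#'   channel over chromatic pixels — sensitive to the dominant stain color
#'   rather than brightness.
#' * AMCE, absolute mean color error: absolute difference of window-mean
#'   opponent-channel values (alpha: red-green, beta: yellow-blue) between
#'   a target (reference) image set and a processed set.
#' * CD, contrast difference: window-averaged grayscale coefficient of
#'   variation (sd/mean) of a normalized image minus that of its
#'   un-normalized counterpart; positive values indicate contrast gain.
#'
#' Population consistency is summarized by the coefficient of variation
#' (CV = sample standard deviation / mean) of each metric across images:
#' the lower the CV, the more color-constant the population.
#'
#' All medians and percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @name cn_quality_metrics
NULL

q95 <- function(x) stats::quantile(x, 0.95, names = FALSE, type = 7)

#' Normalized median intensity of an image
#'
#' @param img RGB image array (0-255).
#' @return scalar in `[0, 1]` (median never exceeds the 95th percentile for
#'   non-negative intensities).
#' @export
nmi <- function(img) {
  a <- gray_mean(img)
  p <- q95(a)
  if (p <= 0) stop_undefined_metric("NMI undefined: 95th percentile intensity is zero")
  stats::median(a) / p
}

#' Normalized median hue of an image
#'
#' Computed over chromatic pixels only (hue is undefined at zero
#' saturation). Hue is treated as a linear quantity in degrees `[0, 360)`.
#'
#' @param img RGB image array (0-255).
#' @return scalar in `[0, 1]`.
#' @export
nmh <- function(img) {
  hv <- rgb_to_hue(img)
  h <- hv$hue[hv$chromatic]
  if (length(h) == 0)
    stop_undefined_metric("NMH undefined: image has no chromatic pixels")
  p <- q95(h)
  if (p <= 0) stop_undefined_metric("NMH undefined: 95th percentile hue is zero")
  stats::median(h) / p
}

# Means (and sds) of non-overlapping w x w windows of a matrix, row-major
# window order; partial edge windows are discarded.
window_stats <- function(x, w, what = c("mean", "both")) {
  what <- match.arg(what)
  nr <- nrow(x) %/% w
  nc <- ncol(x) %/% w
  if (nr < 1 || nc < 1)
    stop_invalid_input("image smaller than one analysis window")
  a <- array(x[seq_len(nr * w), seq_len(nc * w)], dim = c(w, nr, w, nc))
  mu <- as.vector(t(apply(a, c(2, 4), mean)))
  if (what == "mean") return(list(mean = mu))
  sd <- as.vector(t(apply(a, c(2, 4), stats::sd)))
  list(mean = mu, sd = sd)
}

pool_window_means <- function(images, channel_fun, window_size) {
  unlist(lapply(images, function(im) {
    window_stats(channel_fun(im), window_size)$mean
  }), use.names = FALSE)
}

as_image_list <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) list(x)
  else if (is.list(x)) x
  else stop_invalid_input("expected an RGB image or a list of RGB images")
}

#' Absolute mean color error between two image sets
#'
#' Window means of the opponent channels are pooled per set (all complete
#' windows of all images, row-major) and the metric is the absolute
#' difference of the pooled means, reported separately for the red-green
#' (alpha) and yellow-blue (beta) channels.
#'
#' @param target_set target/reference image or list of images.
#' @param processed_set processed image or list of images.
#' @param window_size analysis window side in pixels (default 64).
#' @return named numeric vector `c(amce_alpha =, amce_beta =)`.
#' @export
amce <- function(target_set, processed_set, window_size = 64) {
  target_set <- as_image_list(target_set)
  processed_set <- as_image_list(processed_set)
  if (length(target_set) == 0 || length(processed_set) == 0)
    stop_invalid_input("both image sets must be non-empty")
  if (window_size < 1) stop_invalid_input("window_size must be >= 1")
  labs_t <- lapply(target_set, rgb_to_lab)
  labs_p <- lapply(processed_set, rgb_to_lab)
  chan <- function(k) function(lab) lab[, , k]
  out <- sapply(2:3, function(k) {
    abs(mean(pool_window_means(labs_t, chan(k), window_size)) -
        mean(pool_window_means(labs_p, chan(k), window_size)))
  })
  c(amce_alpha = out[1], amce_beta = out[2])
}

#' Contrast difference between a normalized image and its original
#'
#' Grayscale sd/mean is computed per non-overlapping window and averaged;
#' the value is the normalized image's average minus the un-normalized
#' image's. Windows where either image has zero mean are excluded from
#' both sums.
#'
#' @param normalized,unnormalized RGB image arrays of identical size.
#' @inheritParams amce
#' @return scalar; positive indicates a contrast gain.
#' @export
cd <- function(normalized, unnormalized, window_size = 64) {
  assert_rgb(normalized, "normalized"); assert_rgb(unnormalized, "unnormalized")
  if (!all(dim(normalized) == dim(unnormalized)))
    stop_invalid_input("normalized and unnormalized images must have identical dimensions")
  if (window_size < 1) stop_invalid_input("window_size must be >= 1")
  sn <- window_stats(gray_mean(normalized), window_size, "both")
  su <- window_stats(gray_mean(unnormalized), window_size, "both")
  keep <- sn$mean > 0 & su$mean > 0
  if (!any(keep)) stop_invalid_input("no usable windows (all means are zero)")
  mean(sn$sd[keep] / sn$mean[keep]) - mean(su$sd[keep] / su$mean[keep])
}

metric_or_na <- function(expr) {
  tryCatch(expr, he_undefined_metric = function(e) NA_real_)
}

#' Per-image metric table and population coefficient of variation
#'
#' Computes NMI and NMH for every image, CD against a paired un-normalized
#' image where provided, and per-image AMCE against a target set where
#' provided, then summarizes each metric over the population by mean,
#' sample standard deviation and CV = sd/mean. Images where a metric is
#' undefined are recorded as missing and excluded from the summary, with
#' the count reported.
#'
#' @param images list of RGB images (the population under evaluation).
#' @param image_ids optional character ids; defaults to `img_001`, ...
#'   Rows are ordered by id.
#' @param paired_unnormalized optional list parallel to `images` with the
#'   un-normalized originals (enables CD).
#' @param target_set optional target/reference image list (enables AMCE).
#' @inheritParams amce
#' @return object of class `he_population_report`: list with `per_image`
#'   (data.frame) and `summary` (data.frame of metric, n, mean, sd, cv,
#'   n_missing).
#' @export
population_report <- function(images, image_ids = NULL,
                              paired_unnormalized = NULL, target_set = NULL,
                              window_size = 64) {
  images <- as_image_list(images)
  n <- length(images)
  if (n == 0) stop_invalid_input("images must be a non-empty list")
  if (is.null(image_ids))
    image_ids <- sprintf("img_%03d", seq_len(n))
  if (length(image_ids) != n) stop_invalid_input("image_ids length mismatch")
  if (!is.null(paired_unnormalized) && length(paired_unnormalized) != n)
    stop_invalid_input("paired_unnormalized must parallel images")
  ord <- order(image_ids)
  per <- data.frame(image_id = image_ids[ord], stringsAsFactors = FALSE)
  per$nmi <- vapply(ord, function(i) metric_or_na(nmi(images[[i]])), 0)
  per$nmh <- vapply(ord, function(i) metric_or_na(nmh(images[[i]])), 0)
  if (!is.null(paired_unnormalized))
    per$cd <- vapply(ord, function(i)
      metric_or_na(cd(images[[i]], paired_unnormalized[[i]], window_size)), 0)
  if (!is.null(target_set)) {
    am <- t(vapply(ord, function(i)
      amce(target_set, images[[i]], window_size), c(amce_alpha = 0, amce_beta = 0)))
    per$amce_alpha <- am[, 1]
    per$amce_beta <- am[, 2]
  }
  metrics <- setdiff(names(per), "image_id")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    x <- per[[m]]
    ok <- x[!is.na(x)]
    mu <- mean(ok)
    sd <- if (length(ok) > 1) stats::sd(ok) else 0
    data.frame(metric = m, n = length(ok), mean = mu, sd = sd,
               cv = sd / mu, n_missing = sum(is.na(x)),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_image = per, summary = summ, window_size = window_size),
            class = "he_population_report")
}

#' @export
print.he_population_report <- function(x, ...) {
  cat(sprintf("Population report: %d images, window %d px\n",
              nrow(x$per_image), x$window_size))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a population report as CSV (with summary footer) and JSON
#'
#' The CSV holds the per-image table followed by `mean`, `sd` and `cv`
#' footer rows; the JSON mirrors the full report. Values are written with
#' six significant digits.
#'
#' @param report `he_population_report` object.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!inherits(report, "he_population_report"))
    stop_invalid_input("report must come from population_report()")
  per <- report$per_image
  metrics <- setdiff(names(per), "image_id")
  if (!is.null(csv_path)) {
    tab <- per
    for (m in metrics) tab[[m]] <- fmt_num(tab[[m]])
    for (stat in c("mean", "sd", "cv")) {
      row <- c(stat, vapply(metrics, function(m)
        fmt_num(report$summary[report$summary$metric == m, stat]), ""))
      tab <- rbind(tab, stats::setNames(as.list(row), names(tab)))
    }
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(per_image = per, summary = report$summary,
                              window_size = report$window_size),
                         json_path, dataframe = "rows", digits = 6, na = "null")
  invisible(report)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
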
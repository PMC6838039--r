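#' Reference-based color normalization
#'
#' Four classical color-normalization (CN) methods behind a single
#' fit-reference / apply contract:
#'
#' * `"hs"` histogram specification: per-RGB-channel monotone histogram
#'   matching to the reference channel histograms.
#' * `"rh"` Reinhard color transfer: per-channel mean/standard-deviation
#'   matching in Ruderman l-alpha-beta space.
#' * `"mc"` Macenko spectral matching: stain deconvolution of the query
#'   with its own estimated stain matrix, per-stain rescaling so the robust
#'   maximum concentration matches the reference's, recomposition with the
#'   reference stain matrix.
#' * `"kh"` quantile-mapping stain-channel normalization ("KH-style"): the
#'   query's per-stain concentration distributions are mapped onto the
#'   reference's by a monotone quantile map, then recomposed with the
#'   reference stain matrix. This preserves the defining property of
#'   stain-specific nonlinear color transfer (reference stain-channel
#'   statistics imposed on the query) with a simple monotone map in place
#'   of the original spline-regression formulation.
#'
#' Images normalized externally (e.g. by a GAN) enter the pipeline as a
#' pre-normalized directory; no model fitting is involved for them.
#'
#' @name normalization
NULL

he_methods <- c("hs", "rh", "mc", "kh")

#' Fit a reference model for color normalization
#'
#' Captures, from a single reference image, the statistics each CN method
#' needs at apply time.
#'
#' @param ref reference RGB image array.
#' @param method one of `"hs"`, `"rh"`, `"mc"`, `"kh"`.
#' @param background brightfield intensity (length 1 or 3) used by the
#'   stain-based methods.
#' @param od_threshold,angular_percentile Macenko stain-estimation
#'   parameters, see [estimate_stain_matrix()].
#' @param robust_max_percentile percentile (percent) defining the robust
#'   maximum stain concentration for `"mc"` (default 99).
#' @param kh_probs probability grid for the `"kh"` reference concentration
#'   quantiles.
#' @return object of class `he_reference_model`.
#' @export
fit_reference <- function(ref, method = c("hs", "rh", "mc", "kh"),
                          background = 255,
                          od_threshold = 0.15, angular_percentile = 1,
                          robust_max_percentile = 99,
                          kh_probs = seq(0, 1, by = 0.001)) {
  method <- match.arg(method)
  assert_rgb(ref, "reference")
  bg <- check_background(background)
  params <- switch(method,
    hs = {
      list(histograms = lapply(1:3, function(c)
        tabulate(as.integer(round_half_up(ref[, , c])) + 1L, nbins = 256L)))
    },
    rh = {
      lab <- rgb_to_lab(ref)
      mu <- apply(lab, 3, mean)
      sd <- apply(lab, 3, stats::sd)
      if (any(sd <= 1e-12))
        stop_degenerate_reference("reference has zero variance in an l-alpha-beta channel")
      list(lab_mean = mu, lab_sd = sd)
    },
    mc = {
      V <- estimate_stain_matrix(rgb_to_od(ref, bg), od_threshold, angular_percentile)
      S <- deconvolve(rgb_to_od(ref, bg), V)
      mx <- apply(matrix(S, ncol = 2), 2, stats::quantile,
                  probs = robust_max_percentile / 100, names = FALSE, type = 7)
      if (any(mx <= 0))
        stop_degenerate_reference("reference robust maximum concentration is not positive")
      list(stain_matrix = V, robust_max = mx,
           robust_max_percentile = robust_max_percentile)
    },
    kh = {
      V <- estimate_stain_matrix(rgb_to_od(ref, bg), od_threshold, angular_percentile)
      S <- matrix(deconvolve(rgb_to_od(ref, bg), V), ncol = 2)
      qs <- apply(S, 2, stats::quantile, probs = kh_probs, names = FALSE, type = 7)
      list(stain_matrix = V, conc_quantiles = qs, probs = kh_probs)
    })
  structure(list(method = method, background = bg,
                 od_threshold = od_threshold,
                 angular_percentile = angular_percentile,
                 params = params),
            class = "he_reference_model")
}

assert_model <- function(model, method) {
  if (!inherits(model, "he_reference_model"))
    stop_invalid_input("model must come from fit_reference()")
  if (model$method != method)
    stop_invalid_input(sprintf("model was fitted for method '%s', not '%s'",
                               model$method, method))
  invisible(model)
}

# smallest reference level whose CDF reaches each query level's CDF
hs_lut <- function(query_hist, ref_hist) {
  qc <- cumsum(query_hist) / sum(query_hist)
  rc <- cumsum(ref_hist) / sum(ref_hist)
  idx <- findInterval(qc - 1e-12, rc) + 1L
  pmin(idx, 256L) - 1L
}

#' Apply histogram-specification normalization
#'
#' @param query RGB image array to normalize.
#' @param model reference model fitted with the matching method.
#' @return normalized RGB image array.
#' @export
normalize_hs <- function(query, model) {
  assert_rgb(query, "query"); assert_model(model, "hs")
  out <- query
  for (c in 1:3) {
    q <- as.integer(round_half_up(query[, , c]))
    qh <- tabulate(q + 1L, nbins = 256L)
    lut <- hs_lut(qh, model$params$histograms[[c]])
    out[, , c] <- lut[q + 1L]
  }
  out
}

#' @rdname normalize_hs
#' @export
normalize_rh <- function(query, model) {
  assert_rgb(query, "query"); assert_model(model, "rh")
  lab <- rgb_to_lab(query)
  for (c in 1:3) {
    x <- lab[, , c]
    qm <- mean(x); qs <- stats::sd(x)
    scale <- if (qs > 1e-12) model$params$lab_sd[c] / qs else 1
    lab[, , c] <- (x - qm) * scale + model$params$lab_mean[c]
  }
  lab_to_rgb(lab)
}

#' @rdname normalize_hs
#' @export
normalize_mc <- function(query, model) {
  assert_rgb(query, "query"); assert_model(model, "mc")
  od <- rgb_to_od(query, model$background)
  Vq <- estimate_stain_matrix(od, model$od_threshold, model$angular_percentile)
  S <- deconvolve(od, Vq)
  p <- model$params$robust_max_percentile / 100
  for (k in 1:2) {
    qmax <- stats::quantile(S[, , k], probs = p, names = FALSE, type = 7)
    S[, , k] <- S[, , k] * (model$params$robust_max[k] / max(qmax, 1e-8))
  }
  recompose(model$params$stain_matrix, S, model$background)
}

#' @rdname normalize_hs
#' @export
normalize_kh <- function(query, model) {
  assert_rgb(query, "query"); assert_model(model, "kh")
  od <- rgb_to_od(query, model$background)
  Vq <- estimate_stain_matrix(od, model$od_threshold, model$angular_percentile)
  S <- deconvolve(od, Vq)
  n <- prod(dim(S)[1:2])
  for (k in 1:2) {
    x <- S[, , k]
    p <- (rank(x, ties.method = "average") - 0.5) / n
    S[, , k] <- stats::approx(model$params$probs, model$params$conc_quantiles[, k],
                              xout = p, rule = 2)$y
  }
  recompose(model$params$stain_matrix, S, model$background)
}

#' Normalize an image with a fitted reference model
#'
#' Dispatches to the method the model was fitted for.
#'
#' @inheritParams normalize_hs
#' @export
normalize_image <- function(query, model) {
  if (!inherits(model, "he_reference_model"))
    stop_invalid_input("model must come from fit_reference()")
  switch(model$method,
    hs = normalize_hs(query, model),
    rh = normalize_rh(query, model),
    mc = normalize_mc(query, model),
    kh = normalize_kh(query, model))
}

#' Serialize / restore a reference model as JSON
#'
#' @param model `he_reference_model` object.
#' @param path JSON file path.
#' @export
write_reference_model <- function(model, path) {
  if (!inherits(model, "he_reference_model"))
    stop_invalid_input("model must come from fit_reference()")
  obj <- unclass(model)
  if (!is.null(obj$params$stain_matrix))
    obj$params$stain_matrix <- lapply(1:3, function(r)
      unname(obj$params$stain_matrix[r, ]))
  if (!is.null(obj$params$conc_quantiles))
    obj$params$conc_quantiles <- lapply(1:2, function(k)
      unname(obj$params$conc_quantiles[, k]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$params$stain_matrix)) {
    v <- obj$params$stain_matrix
    V <- if (is.matrix(v)) v else do.call(rbind, lapply(v, as.numeric))
    obj$params$stain_matrix <- make_stain_matrix(V)
  }
  if (!is.null(obj$params$conc_quantiles)) {
    q <- obj$params$conc_quantiles
    if (is.matrix(q)) {
      if (nrow(q) == 2L && ncol(q) != 2L) q <- t(q)  # JSON arrays are row-major
    } else q <- do.call(cbind, lapply(q, as.numeric))
    obj$params$conc_quantiles <- q
  }
  if (!is.null(obj$params$histograms)) {
    h <- obj$params$histograms
    if (is.matrix(h)) {
      if (ncol(h) == 3L && nrow(h) != 3L) h <- t(h)
      h <- lapply(seq_len(nrow(h)), function(r) as.numeric(h[r, ]))
    } else h <- lapply(h, as.numeric)
    obj$params$histograms <- h
  }
  structure(obj, class = "he_reference_model")
}
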
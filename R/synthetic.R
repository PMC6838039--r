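#' Synthetic multicenter H&E scenes
#'
#' Seeded generator of H&E-like regions of interest with full ground
#' truth: a ternary label map (background / nucleus boundary / nucleus),
#' per-stain concentration fields, and the stain matrix used for
#' Beer-Lambert rendering. Simulated "centers" differ in their stain
#' matrix (rotated by a bounded angle) and global staining intensity,
#' emulating the chromatic drift between imaging sites that color
#' normalization is meant to remove. A simulated ternary predictor stands
#' in for trained segmentation networks so ensembling and evaluation can
#' be exercised closed-loop.
#'
#' All randomness is drawn from per-operation streams derived from the
#' user seed, so every artifact is a pure function of (parameters, seed).
#'
#' @name synthetic_data
NULL

# Run code under a derived, restorable RNG state.
with_stream <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op))) %% 100003L
  set.seed((as.integer(seed) %% 20000003L) * 101L + h)
  force(code)
}

#' Default H&E stain matrix
#'
#' Published optical-density vectors for hematoxylin (0.65, 0.70, 0.29)
#' and eosin (0.07, 0.99, 0.11), normalized to unit length.
#'
#' @return 3x2 stain matrix.
#' @export
default_stain_matrix <- function() {
  make_stain_matrix(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)))
}

#' Default scene parameters
#'
#' 256 x 256 px field with 12 elliptical nuclei of semi-axis 6-12 px, a
#' 2 px boundary ring, hematoxylin concentrated in nuclei and eosin in a
#' textured stroma, rendered against a 255 brightfield with optical
#' density noise of standard deviation 0.01 (a quiet-camera level that
#' leaves stain chromaticity clearly recoverable).
#'
#' @param ... overrides for individual fields.
#' @return named list of parameters.
#' @export
scene_params <- function(...) {
  p <- list(
    height = 256L, width = 256L,
    n_nuclei = 20L,
    radius_range = c(6, 12),
    boundary_px = 2L,
    background = 255,
    noise_sd = 0.01,
    conc_nucleus_h = 0.9,
    conc_stroma_h = 0.18,
    conc_nucleus_e = 0.1,
    conc_stroma_e = 0.35,
    conc_rim_h = 0.7,
    stroma_texture = 0.12,
    stroma_h_texture = 0.18,
    stain_matrix = default_stain_matrix(),
    max_attempts = 200L)
  over <- list(...)
  p[names(over)] <- over
  p
}

# Binary ellipse mask on an H x W grid.
ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  matrix(as.logical(out), nrow(mask), ncol(mask))
}

# Smooth positive texture field in [-1, 1]-ish range: blurred white noise,
# rescaled to unit standard deviation.
smooth_noise <- function(H, W, sigma = 6) {
  z <- matrix(stats::rnorm(H * W), H, W)
  s <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = sigma))
  s / max(stats::sd(s), 1e-12)
}

#' Generate a synthetic H&E scene
#'
#' Places non-overlapping random ellipses as nuclei (rejection sampling
#' with a bounded number of attempts per nucleus), surrounds each with a
#' boundary ring, and assigns stain concentrations: hematoxylin high
#' inside nuclei with an accentuated (darker) rim, eosin moderate in a
#' smoothly textured stroma.
#'
#' @param params parameter list from [scene_params()].
#' @param seed integer seed; the scene is a pure function of
#'   (params, seed).
#' @return object of class `he_scene`: list with `labels` (ternary
#'   matrix), `nuclei_mask`, `concentrations` (height x width x 2),
#'   `stain_matrix`, `params`, `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  H <- params$height; W <- params$width
  if (min(params$radius_range) <= params$boundary_px || params$boundary_px < 1)
    stop_invalid_input("need radii > boundary_px >= 1")
  with_stream(seed, "scene", {
    nuclei <- matrix(FALSE, H, W)
    occupied <- matrix(FALSE, H, W)
    placed <- 0L
    margin <- ceiling(max(params$radius_range)) + params$boundary_px + 1
    for (i in seq_len(params$n_nuclei)) {
      ok <- FALSE
      for (att in seq_len(params$max_attempts)) {
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin)
        a <- stats::runif(1, params$radius_range[1], params$radius_range[2])
        b <- stats::runif(1, params$radius_range[1], params$radius_range[2])
        th <- stats::runif(1, 0, pi)
        e <- ellipse_mask(H, W, cy, cx, a, b, th)
        halo <- dilate_disc(e, params$boundary_px + 1L)
        if (!any(halo & occupied)) {
          nuclei <- nuclei | e
          occupied <- occupied | halo
          placed <- placed + 1L
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_placement(sprintf(
          "could only place %d of %d nuclei at this density", placed, params$n_nuclei),
          achieved = placed)
    }
    boundary <- dilate_disc(nuclei, params$boundary_px) & !nuclei
    labels <- matrix(CLASS_BACKGROUND, H, W)
    labels[boundary] <- CLASS_BOUNDARY
    labels[nuclei] <- CLASS_NUCLEI
    stroma_tex <- smooth_noise(H, W)
    stroma_tex_h <- smooth_noise(H, W)
    conc <- array(0, dim = c(H, W, 2L))
    # hematoxylin bleeds into the stroma with smoothly varying uptake, so
    # each image spans a wide range of H:E mixing ratios (and hence hues),
    # as real tissue does
    ch <- params$conc_stroma_h + params$stroma_h_texture * stroma_tex_h
    ch[nuclei] <- params$conc_nucleus_h
    ch[boundary] <- params$conc_rim_h
    ce <- params$conc_stroma_e + params$stroma_texture * stroma_tex
    ce[nuclei | boundary] <- params$conc_nucleus_e
    conc[, , 1] <- pmax(ch, 0)
    conc[, , 2] <- pmax(ce, 0)
    structure(list(labels = labels, nuclei_mask = nuclei,
                   concentrations = conc,
                   stain_matrix = params$stain_matrix,
                   params = params, seed = as.integer(seed)),
              class = "he_scene")
  })
}

#' Render a scene to RGB through the Beer-Lambert law
#'
#' `RGB = od_to_rgb(V %*% S + noise)` with seeded Gaussian optical-density
#' noise (clamped at zero).
#'
#' @param scene `he_scene` object.
#' @param noise_sd OD noise standard deviation; defaults to the scene's
#'   `noise_sd` parameter.
#' @return RGB image array.
#' @export
render_scene <- function(scene, noise_sd = NULL) {
  if (!inherits(scene, "he_scene")) stop_invalid_input("scene must come from generate_scene()")
  if (is.null(noise_sd)) noise_sd <- scene$params$noise_sd
  d <- dim(scene$concentrations)
  od <- matrix(scene$concentrations, ncol = 2L) %*% t(scene$stain_matrix)
  if (noise_sd > 0) {
    od <- od + with_stream(scene$seed, "render",
                           matrix(stats::rnorm(length(od), 0, noise_sd), nrow(od)))
  }
  od_to_rgb(array(pmax(od, 0), dim = c(d[1], d[2], 3L)), scene$params$background)
}

# Rotate a unit stain vector by angle_deg toward a random in-plane
# direction, resampling while any component would go negative.
perturb_stain_vector <- function(v, angle_deg, max_tries = 50L) {
  if (angle_deg <= 0) return(v)
  for (i in seq_len(max_tries)) {
    w <- stats::rnorm(3)
    w <- w - sum(w * v) * v
    nw <- sqrt(sum(w^2))
    if (nw < 1e-9) next
    w <- w / nw
    phi <- stats::runif(1, 0, angle_deg) * pi / 180
    u <- cos(phi) * v + sin(phi) * w
    if (all(u >= 0)) return(u / sqrt(sum(u^2)))
  }
  v  # fall back to the unperturbed vector
}

#' Generate a multicenter synthetic image set
#'
#' Each center receives a stain matrix perturbed from the base matrix by
#' up to `stain_jitter_deg` per column, a global staining-intensity factor
#' and a brightfield offset; `scenes_per_center` scenes are generated and
#' rendered per center.
#'
#' @param n_centers number of simulated centers.
#' @param scenes_per_center images per center.
#' @param base_params scene parameters shared by all centers.
#' @param stain_jitter_deg maximum per-column stain rotation (degrees).
#' @param seed integer seed.
#' @return list of records: `center_id`, `image` (RGB array), `scene`
#'   (`he_scene`).
#' @export
generate_multicenter <- function(n_centers = 3L, scenes_per_center = 10L,
                                 base_params = scene_params(),
                                 stain_jitter_deg = 15, seed = 1L) {
  if (stain_jitter_deg < 0) stop_invalid_input("stain_jitter_deg must be >= 0")
  centers <- with_stream(seed, "centers", {
    # Scanner tone curve (gamma) and illumination warmth are drawn by
    # stratified (Latin-hypercube-style) sampling: with a handful of
    # centers, independent draws can produce near-identical scanners,
    # which would no longer pose the multicenter problem being simulated.
    gamma_strata <- sample(seq_len(n_centers))
    warmth_strata <- sample(seq_len(n_centers))
    # Center effects emulate the classic sources of multicenter H&E
    # variability: overall staining intensity (section thickness,
    # staining time), per-dye protocol differences, scanner illumination
    # color (warm/cool brightfield white point), and the scanner tone
    # curve (gamma). All scanner/protocol draws happen before the stain
    # jitter so that sets generated at different jitter levels (but the
    # same seed) share identical scanner conditions.
    scanners <- lapply(seq_len(n_centers), function(k) {
      gamma <- stats::runif(1, 0.8 + 0.45 * (gamma_strata[k] - 1) / n_centers,
                            0.8 + 0.45 * gamma_strata[k] / n_centers)
      warmth <- stats::runif(1, -24 + 48 * (warmth_strata[k] - 1) / n_centers,
                             -24 + 48 * warmth_strata[k] / n_centers)
      white <- stats::runif(1, 235, 243)
      bg <- round(c(white + warmth / 2, white, white - warmth / 2))
      list(intensity = stats::runif(1, 0.75, 1.25),
           intensity_h = stats::runif(1, 0.85, 1.15),
           intensity_e = stats::runif(1, 0.85, 1.15),
           gamma = gamma,
           background = pmin(pmax(bg, 200), 255))
    })
    lapply(seq_len(n_centers), function(k) {
      V <- base_params$stain_matrix
      # resample jitters that would let eosin end up bluer than
      # hematoxylin: such a matrix no longer depicts an H&E stain pair
      for (try in 1:50) {
        V2 <- cbind(perturb_stain_vector(V[, 1], stain_jitter_deg),
                    perturb_stain_vector(V[, 2], stain_jitter_deg))
        if (V2[3, 1] > V2[3, 2] + 0.10) break
        V2 <- V
      }
      c(list(stain_matrix = make_stain_matrix(V2)), scanners[[k]])
    })
  })
  out <- list()
  for (k in seq_len(n_centers)) {
    for (j in seq_len(scenes_per_center)) {
      p <- base_params
      ctr <- centers[[k]]
      p$stain_matrix <- ctr$stain_matrix
      p$background <- ctr$background
      fh <- ctr$intensity * ctr$intensity_h
      fe <- ctr$intensity * ctr$intensity_e
      for (f in c("conc_nucleus_h", "conc_stroma_h", "conc_rim_h", "stroma_h_texture"))
        p[[f]] <- p[[f]] * fh
      for (f in c("conc_nucleus_e", "conc_stroma_e", "stroma_texture"))
        p[[f]] <- p[[f]] * fe
      sc_seed <- (as.integer(seed) %% 1000003L) * 1009L + k * 211L + j
      scene <- generate_scene(p, seed = sc_seed)
      img <- render_scene(scene)
      img <- clamp255(round_half_up(255 * (img / 255)^ctr$gamma))
      out[[length(out) + 1L]] <- list(center_id = k, image = img, scene = scene)
    }
  }
  out
}

#' Simulate a ternary nuclei predictor
#'
#' Produces a probability map concentrated on the ground-truth class with
#' seeded corruption: each pixel's class is flipped to a random other
#' class with probability `flip_prob`, the chosen class receives
#' probability mass `sharpness` (the rest split evenly), and truncated
#' Gaussian noise of sd `prob_noise` is added per channel. `"softmax"`
#' style renormalizes channels to sum to one; `"sigmoid"` leaves them
#' independent.
#'
#' @param scene `he_scene` object.
#' @param flip_prob per-pixel class flip probability in `[0, 1)`.
#' @param sharpness probability mass on the (possibly flipped) class, in
#'   `(1/3, 1]`.
#' @param prob_noise channel noise standard deviation.
#' @param style `"softmax"` or `"sigmoid"`.
#' @param seed integer seed (independent predictors = different seeds).
#' @return ternary probability map with a `source_tag` attribute.
#' @export
simulate_predictor <- function(scene, flip_prob = 0.1, sharpness = 0.9,
                               prob_noise = 0.05,
                               style = c("softmax", "sigmoid"), seed = 1L) {
  if (!inherits(scene, "he_scene")) stop_invalid_input("scene must come from generate_scene()")
  style <- match.arg(style)
  if (flip_prob < 0 || flip_prob >= 1) stop_invalid_input("flip_prob must lie in [0, 1)")
  if (sharpness <= 1 / 3 || sharpness > 1)
    stop_invalid_input("sharpness must lie in (1/3, 1]")
  H <- nrow(scene$labels); W <- ncol(scene$labels)
  with_stream(seed, "predict", {
    cls <- as.vector(scene$labels)
    flip <- stats::runif(H * W) < flip_prob
    if (any(flip)) {
      shift <- sample(1:2, sum(flip), replace = TRUE)
      cls[flip] <- (cls[flip] + shift) %% 3L
    }
    p <- matrix((1 - sharpness) / 2, H * W, 3L)
    p[cbind(seq_len(H * W), cls + 1L)] <- sharpness
    if (prob_noise > 0)
      p <- p + matrix(stats::rnorm(H * W * 3L, 0, prob_noise), ncol = 3L)
    p <- pmin(pmax(p, 0), 1)
    if (style == "softmax") {
      s <- rowSums(p)
      zero <- s < 1e-12
      if (any(zero)) { p[zero, ] <- 1 / 3; s[zero] <- 1 }
      p <- p / s
    }
    out <- array(p, dim = c(H, W, 3L))
    attr(out, "source_tag") <- sprintf("SIM-%d", as.integer(seed))
    out
  })
}

#' Write a multicenter set to disk
#'
#' Images as PNG, ternary labels as class-indexed PNG, and a JSON metadata
#' file per image (center id, seed, stain matrix).
#'
#' @param records list from [generate_multicenter()].
#' @param dir output directory (created if missing).
#' @export
write_multicenter <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    stem <- sprintf("c%02d_s%03d", rec$center_id, i)
    write_image(rec$image, file.path(dir, paste0(stem, ".png")))
    write_label_image(rec$scene$labels, file.path(dir, paste0(stem, "_labels.png")))
    jsonlite::write_json(list(
      center_id = rec$center_id, seed = rec$scene$seed,
      stain_matrix = lapply(1:3, function(r) unname(rec$scene$stain_matrix[r, ]))),
      file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
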
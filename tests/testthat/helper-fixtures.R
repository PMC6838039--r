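# Shared fixtures built in code at test time.

random_rgb <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  as_rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

uniform_rgb <- function(rgb, h = 8, w = 8) {
  as_rgb_image(array(rep(rgb, each = h * w), c(h, w, 3)))
}

small_scene <- function(seed = 1, h = 96L, w = 96L, n = 5L) {
  generate_scene(scene_params(height = h, width = w, n_nuclei = n,
                              radius_range = c(5, 9)), seed = seed)
}

random_prob_map <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

random_mask <- function(h = 16, w = 16, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w) < p, h, w)
}
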
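# shared fixtures, all generated in code

# a random symmetric weight graph on an n x m grid, built from a random
# guide image so the weights are non-trivial
random_graph <- function(n, m = n, seed = 1, h = 0.5, k = 6) {
  guide <- withr::with_seed(seed, matrix(runif(n * m), n, m))
  compute_weights(guide, patch_radius = 1, search_radius = 2, h = h,
                  sigma_patch = 1, neighbors_kept = k)
}

random_image <- function(n, m = n, seed = 1) {
  withr::with_seed(seed, matrix(runif(n * m), n, m))
}

random_field <- function(g, seed = 1, sd = 1) {
  withr::with_seed(seed, stats::rnorm(length(g$i), sd = sd))
}

# a small undersampled noisy measurement for solver tests; below the
# phantom generator's minimum size a seeded disk-on-background image is used
small_measurement <- function(n = 16, ratio = 0.35, seed = 1, noise = 0.01) {
  u <- if (n >= 16) make_phantom("piecewise", n, seed) else {
    ax <- seq(-1, 1, length.out = n)
    disk <- outer(ax^2, ax^2, "+") <= 0.5
    withr::with_seed(seed, 0.1 + 0.7 * disk + 0.02 * matrix(runif(n * n), n))
  }
  mask <- make_vardens_mask(n, ratio, decay = 4, center_fraction = 0.1,
                            seed = seed)
  m <- forward_measure(u, mask)
  if (noise > 0) m <- add_noise(m, "gaussian", noise, seed + 100)
  list(u = u, mask = mask, m = m)
}

edge_inner <- function(a, b) sum(a * b)
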
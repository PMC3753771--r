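# patch-similarity weights and the discrete nonlocal calculus

test_that("constant guide yields all-ones weights", {
  g <- compute_weights(matrix(0.4, 12, 12), patch_radius = 1,
                       search_radius = 2, h = 0.3)
  expect_true(all(g$w == 1))
})

test_that("weights match the brute-force patch-distance oracle on 3x3", {
  guide <- random_image(3, seed = 7)
  g <- compute_weights(guide, patch_radius = 1, search_radius = 1, h = 1,
                       sigma_patch = 1, neighbors_kept = 8)
  # oracle: literal Gaussian-weighted squared distance between patches read
  # from the mirror-padded image
  k1 <- stats::dnorm(-1:1, sd = 1); k1 <- k1 / sum(k1)
  K2 <- outer(k1, k1)
  idx <- c(1, 1:3, 3)                      # mirror padding by 2 in each axis
  gp <- guide[c(2, idx, 2), c(2, idx, 2)]
  patch <- function(r, c) gp[(r + 1):(r + 3), (c + 1):(c + 3)]
  for (e in seq_along(g$i)) {
    ri <- (g$i[e] - 1) %% 3 + 1; ci <- (g$i[e] - 1) %/% 3 + 1
    rj <- (g$j[e] - 1) %% 3 + 1; cj <- (g$j[e] - 1) %/% 3 + 1
    D <- sum(K2 * (patch(ri, ci) - patch(rj, cj))^2)
    expect_equal(g$w[e], exp(-D), tolerance = 1e-12)
  }
})

test_that("graphs are symmetric with weights in (0, 1] and no self-edges", {
  for (seed in 1:3) {
    g <- random_graph(10, seed = seed)
    expect_true(all(g$w > 0 & g$w <= 1))
    expect_true(all(g$i != g$j))
    expect_gte(min(tabulate(g$i, g$npix)), 1)    # every pixel has a neighbour
    # symmetry: reverse of every edge exists with the same weight
    npix <- g$npix
    key <- (as.numeric(g$i) - 1) * npix + as.numeric(g$j)
    rev <- match((as.numeric(g$j) - 1) * npix + as.numeric(g$i), key)
    expect_false(anyNA(rev))
    expect_equal(max(abs(g$w - g$w[rev])), 0)
  }
  expect_error(compute_weights(random_image(8), patch_radius = 1,
                               search_radius = 2, h = 0), "h")
})

test_that("nonlocal gradient is linear and vanishes on constants", {
  g <- random_graph(8, seed = 2)
  u <- random_image(8, seed = 3)
  expect_true(all(nl_gradient(matrix(2, 8, 8), g) == 0))
  expect_equal(nl_gradient(3 * u, g), 3 * nl_gradient(u, g), tolerance = 1e-12)
  # offset invariance of gradient and its norm
  expect_equal(nl_gradient(u + 5, g), nl_gradient(u, g), tolerance = 1e-10)
  expect_equal(nl_gradient_norm(u + 5, g), nl_gradient_norm(u, g),
               tolerance = 1e-10)
})

test_that("gradient entries and norms match a hand edge loop", {
  g <- random_graph(4, seed = 4)
  u <- random_image(4, seed = 5)
  q <- nl_gradient(u, g)
  for (e in seq_along(g$i))
    expect_equal(q[e], (u[g$j[e]] - u[g$i[e]]) * sqrt(g$w[e]),
                 tolerance = 1e-14)
  nrm <- nl_gradient_norm(u, g)
  for (p in seq_len(g$npix)) {
    sel <- g$i == p
    expect_equal(nrm[p], sqrt(sum((u[g$j[sel]] - u[p])^2 * g$w[sel])),
                 tolerance = 1e-12)
  }
})

test_that("divergence is the exact negative adjoint of the gradient", {
  for (seed in 1:50) {
    g <- random_graph(12, seed = seed, h = 0.3)
    u <- random_image(12, seed = seed + 500)
    q <- random_field(g, seed = seed + 1000)
    lhs <- edge_inner(nl_gradient(u, g), q)
    rhs <- -sum(u * nl_divergence(q, g))
    expect_lt(abs(lhs - rhs),
              1e-10 * sqrt(sum(u^2)) * sqrt(sum(q^2)) + 1e-14)
  }
})

test_that("divergence kills symmetric fields and zero fields", {
  g <- random_graph(8, seed = 6)
  expect_true(all(nl_divergence(numeric(length(g$i)), g) == 0))
  # q_ij = q_ji: build by symmetrizing a random field over reverse edges
  key <- (as.numeric(g$i) - 1) * g$npix + as.numeric(g$j)
  rev <- match((as.numeric(g$j) - 1) * g$npix + as.numeric(g$i), key)
  q <- random_field(g, seed = 9)
  qs <- (q + q[rev]) / 2
  expect_lt(max(abs(nl_divergence(qs, g))), 1e-12)
})

test_that("laplacian identities hold", {
  g <- random_graph(9, seed = 11)
  u <- random_image(9, seed = 12)
  expect_true(all(nl_laplacian(matrix(1, 9, 9), g) == 0))
  # Lap = div(grad)/2 on a symmetric graph
  expect_equal(nl_laplacian(u, g),
               nl_divergence(nl_gradient(u, g), g) / 2, tolerance = 1e-10)
  # total flux cancels pairwise for symmetric weights
  expect_lt(abs(sum(nl_laplacian(u, g))), 1e-12)
})

test_that("forward-difference graph reproduces the isotropic TV magnitude", {
  u <- random_image(10, seed = 13)
  g <- tv_graph(10)
  dx <- rbind(u[-1, ] - u[-10, ], 0)
  dy <- cbind(u[, -1] - u[, -10], 0)
  expect_equal(nl_gradient_norm(u, g), sqrt(dx^2 + dy^2), tolerance = 1e-12)
})

test_that("graphs survive a triplet-file round trip", {
  g <- random_graph(6, seed = 14)
  path <- tempfile(fileext = ".tsv")
  save_graph(g, path)
  g2 <- load_graph(path)
  expect_equal(g2$i, g$i)
  expect_equal(g2$j, g$j)
  expect_equal(g2$w, g$w, tolerance = 1e-12)
  expect_equal(g2$dim, g$dim)
  expect_true(g2$symmetric)
})
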
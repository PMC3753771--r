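# shrinkage, split Bregman sub-steps, and the full NLTV solver

test_that("scalar shrinkage matches its closed form on a grid", {
  xs <- seq(-3, 3, by = 0.25)
  lams <- c(0, 0.1, 0.5, 1, 2)
  for (lam in lams) {
    expected <- sign(xs) * pmax(abs(xs) - lam, 0)
    expect_equal(shrink(xs, lam), expected, tolerance = 1e-15)
  }
  expect_identical(shrink(0, 0.5), 0)
  expect_equal(shrink(2.0, 0.5), 1.5)
  expect_equal(shrink(0.3, 0.5), 0)
  expect_equal(shrink(-2.0, 0.5), -1.5)
  expect_error(shrink(1, -0.1), "nonnegative")
})

make_state <- function(n = 16, seed = 1, with_db = TRUE) {
  s <- small_measurement(n, seed = seed)
  g <- compute_weights(zero_fill_recon(s$m), patch_radius = 1,
                       search_radius = 2, h = 0.1, neighbors_kept = 6)
  d <- if (with_db) random_field(g, seed + 1, sd = 0.1) else numeric(length(g$i))
  b <- if (with_db) random_field(g, seed + 2, sd = 0.1) else numeric(length(g$i))
  st <- solver_state(zero_fill_recon(s$m), s$m$values, s$mask, g, d = d, b = b)
  list(st = st, s = s, g = g)
}

test_that("d-update is the exact groupwise shrinkage minimizer", {
  f <- make_state(12, seed = 3)
  p <- solver_params(gamma = 5)
  d <- d_update(f$st, p)
  s <- nl_gradient(f$st$u, f$g) + f$st$b
  n_i <- nltvrecon:::nl_group_norm(s, f$g)
  # group norm of the output equals shrink(n_i, 1/gamma) exactly
  expect_equal(nltvrecon:::nl_group_norm(d, f$g), shrink(n_i, 1 / p$gamma),
               tolerance = 1e-12)
  # zero signal gives zero d
  st0 <- f$st; st0$b[] <- 0; st0$u <- matrix(1, 12, 12)
  expect_true(all(d_update(st0, p) == 0))
})

test_that("single-edge groups reduce d-update to scalar shrinkage", {
  # two-pixel graph: one edge each way
  g <- nltvrecon:::new_nl_graph(1L, 2L, 0.81, dim = c(1L, 2L),
                                symmetrize = TRUE)
  u <- matrix(c(0, 1), 1, 2)
  b <- c(0.3, -0.2)
  st <- solver_state(u, matrix(0 + 0i, 1, 2), matrix(TRUE, 1, 2), g, b = b)
  p <- solver_params(gamma = 2)
  d <- d_update(st, p)
  s <- (u[g$j] - u[g$i]) * sqrt(0.81) + b
  expect_equal(d, shrink(s, 1 / p$gamma), tolerance = 1e-14)
})

test_that("b-update matches a per-edge loop and its fixed-point algebra", {
  f <- make_state(10, seed = 5)
  f$st$d <- d_update(f$st, solver_params())
  b2 <- b_update(f$st)
  grad <- nl_gradient(f$st$u, f$g)
  for (e in sample(seq_along(f$g$i), 25))
    expect_equal(b2[e], f$st$b[e] + grad[e] - f$st$d[e], tolerance = 1e-14)
  # d = grad u + b  =>  new b = 0
  st <- f$st; st$d <- grad + st$b
  expect_lt(max(abs(b_update(st))), 1e-14)
  # all-zero state stays zero
  st$u[] <- 0; st$d[] <- 0; st$b[] <- 0
  expect_true(all(b_update(st) == 0))
})

test_that("bregman refresh updates acquired entries only", {
  f <- make_state(12, seed = 7)
  v_obs <- f$s$m
  vk1 <- bregman_refresh(f$st, v_obs)
  # dense oracle
  dense <- f$st$vk + v_obs$values - nltvrecon:::fft2u(f$st$u)
  expect_equal(vk1[f$s$mask], dense[f$s$mask], tolerance = 1e-12)
  expect_true(all(vk1[!f$s$mask] == 0))
  # consistent iterate leaves v^k unchanged
  st <- f$st
  st$vk <- nltvrecon:::fft2u(st$u); st$vk[!f$s$mask] <- 0
  v_cons <- v_obs; v_cons$values <- st$vk
  expect_equal(bregman_refresh(st, v_cons), st$vk, tolerance = 1e-12)
  # first refresh from v0 = v with u = 0 doubles the data
  st0 <- f$st; st0$u[] <- 0; st0$vk <- v_obs$values
  expect_equal(bregman_refresh(st0, v_obs), 2 * v_obs$values, tolerance = 1e-12)
})

test_that("u-update decreases the quadratic subproblem and solves it", {
  f <- make_state(16, seed = 9)
  p <- solver_params(mu = 50, gamma = 5)
  quad <- function(u) {
    st <- f$st; st$u <- u
    objective(st, p) - sum(nltvrecon:::nl_group_norm(st$d, f$g))
  }
  q0 <- quad(f$st$u)
  u1 <- u_update(f$st, p, sweeps = 1)
  expect_lte(quad(u1), q0 + 1e-12)
  # sweep-by-sweep monotonicity
  st <- f$st
  for (s in 1:5) {
    un <- u_update(st, p, sweeps = 1)
    expect_lte(quad(un), quad(st$u) + 1e-12)
    st$u <- un
  }
  # optimality residual of the normal equations after convergence
  un <- u_update(f$st, p, sweeps = 300)
  grad_f <- p$gamma * nltvrecon:::nl_grad_t(
              nl_gradient(un, f$g) + f$st$b - f$st$d, f$g) +
            p$mu * (nltvrecon:::ktk_apply(un, f$s$mask) -
                    Re(nltvrecon:::ifft2u(f$st$vk)))
  expect_lt(max(abs(grad_f)), 1e-6)
  # jacobi flavour also descends
  pj <- solver_params(mu = 50, gamma = 5, sweep_type = "jacobi")
  expect_lte(quad(u_update(f$st, pj, sweeps = 1)), q0 + 1e-12)
})

test_that("objective matches a dense oracle on 8x8", {
  f <- make_state(8, seed = 11)
  p <- solver_params(mu = 30, gamma = 4)
  got <- objective(f$st, p)
  # dense evaluation from first principles
  g <- f$g; st <- f$st
  l1 <- 0
  for (px in seq_len(g$npix)) {
    sel <- g$i == px
    l1 <- l1 + sqrt(sum(st$d[sel]^2))
  }
  grad <- (st$u[g$j] - st$u[g$i]) * sqrt(g$w)
  quad <- sum((st$d - grad - st$b)^2)
  Ku <- stats::fft(st$u) / 8
  resid <- Ku * f$s$mask - st$vk
  want <- l1 + p$gamma / 2 * quad + p$mu / 2 * sum(Mod(resid)^2)
  expect_equal(got, want, tolerance = 1e-10)
  # homogeneity of the L1 term
  st0 <- st; st0$u[] <- 0; st0$b[] <- 0; st0$vk[] <- 0
  st2 <- st0; st2$d <- 2 * st0$d
  l1_0 <- objective(st0, p) - p$gamma / 2 * sum(st0$d^2)
  l1_2 <- objective(st2, p) - p$gamma / 2 * sum(st2$d^2)
  expect_equal(l1_2, 2 * l1_0, tolerance = 1e-10)
  # all-zero state with zero data has zero objective
  st0$d[] <- 0
  expect_equal(objective(st0, p), 0)
})

test_that("NLTV solver is deterministic and converges on full data", {
  u <- make_phantom("piecewise", 32, 1)
  m <- forward_measure(u, full_mask(32))
  g <- compute_weights(zero_fill_recon(m), h = 0.05)
  f1 <- reconstruct_nltv(m, g, solver_params(n_outer = 10))
  f2 <- reconstruct_nltv(m, g, solver_params(n_outer = 10))
  expect_identical(f1$image, f2$image)
  expect_lt(relative_error(u, f1$image), 1)
  # objective decreases across the u -> d sub-steps within every sweep
  expect_true(all(f1$history$obj_after_u <= f1$history$obj_start + 1e-9))
  expect_true(all(f1$history$obj_after_d <= f1$history$obj_after_u + 1e-9))
})

test_that("solver reports divergence with the iteration index", {
  s <- small_measurement(16, seed = 2)
  g <- compute_weights(zero_fill_recon(s$m), patch_radius = 1,
                       search_radius = 2, h = 0.1)
  bad <- s$m
  bad$values[s$mask][1] <- NaN + 0i
  expect_error(reconstruct_nltv(bad, g, solver_params(n_outer = 2)),
               "diverged at outer iteration")
})
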
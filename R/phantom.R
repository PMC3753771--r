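#' Generate a synthetic square phantom image
#'
#' Produces a deterministic ground-truth image for reconstruction
#' experiments. Three kinds are available:
#'
#' * `"piecewise"` — a piecewise-constant scene (background plus at least
#'   three constant regions with well-separated intensities), the classic
#'   setting where total-variation regularization excels;
#' * `"textured"` — the same scene with a band-limited pseudo-random texture
#'   superimposed on two of the regions, so that the difference between local
#'   TV (which flattens texture) and nonlocal TV (which preserves it) is
#'   observable;
#' * `"shepp_logan"` — a modified Shepp-Logan head phantom (ten ellipses with
#'   the usual high-contrast intensity assignments).
#'
#' Intensities lie in \[0, 1\]. The output carries a `"regions"` attribute
#' (an integer label matrix, 0 = background) for the piecewise and textured
#' kinds, so per-region statistics can be computed.
#'
#' @param kind one of `"piecewise"`, `"textured"`, `"shepp_logan"`.
#' @param size side length in pixels (square image), at least 16.
#' @param seed integer seed; the same `(kind, size, seed)` always yields a
#'   bit-identical image.
#' @return a `size` x `size` numeric matrix with values in \[0, 1\].
#' @examples
#' u <- make_phantom("textured", 64, seed = 1)
#' range(u)
#' @export
make_phantom <- function(kind = c("piecewise", "textured", "shepp_logan"),
                         size, seed = 0L) {
  kind <- match.arg(kind)
  stop_if(!is.numeric(size) || length(size) != 1L || size < 16,
          "size must be a single integer >= 16")
  size <- as.integer(size)
  switch(kind,
         piecewise   = phantom_piecewise(size, seed, textured = FALSE),
         textured    = phantom_piecewise(size, seed, textured = TRUE),
         shepp_logan = phantom_shepp_logan(size))
}

phantom_piecewise <- function(n, seed, textured) {
  # normalized coordinates in [-1, 1]
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(ax, n, n)          # varies along rows
  Y <- matrix(ax, n, n, byrow = TRUE)

  with_seed(seed, {
    # intensities drawn from disjoint ranges so regions stay distinct
    a_bg   <- runif(1, 0.02, 0.08)
    a_disk <- runif(1, 0.70, 0.90)
    a_rect <- runif(1, 0.40, 0.60)
    a_spot <- runif(1, 0.15, 0.30)

    u <- matrix(a_bg, n, n)
    lab <- matrix(0L, n, n)

    disk <- (X^2 + Y^2) <= 0.72^2
    u[disk] <- a_disk; lab[disk] <- 1L

    rect <- X >= -0.45 & X <= 0.05 & Y >= -0.50 & Y <= -0.10
    u[rect] <- a_rect; lab[rect] <- 2L

    spot <- ((X - 0.35)^2 + (Y - 0.35)^2) <= 0.18^2
    u[spot] <- a_spot; lab[spot] <- 3L

    if (textured) {
      # band-limited texture: white noise filtered by a Gaussian annulus in
      # the frequency domain, added inside regions 1 and 2
      tex <- bandlimited_noise(n, rho0 = 0.18, rho_sd = 0.05)
      sel <- lab == 1L | lab == 2L
      u[sel] <- u[sel] + 0.07 * tex[sel]
    }

    u <- pmin(pmax(u, 0), 1)
    attr(u, "regions") <- lab
    attr(u, "meta") <- sprintf("%s phantom, n=%d, seed=%d",
                               if (textured) "textured" else "piecewise", n, seed)
    u
  })
}

# unit-variance pseudo-random field whose spectrum is a Gaussian annulus
# centred at normalized radial frequency rho0 (cycles/pixel in [0, 0.5])
bandlimited_noise <- function(n, rho0, rho_sd) {
  f <- fft_freq(n)              # signed frequencies in cycles/pixel
  R <- sqrt(outer(f^2, f^2, "+"))
  H <- exp(-(R - rho0)^2 / (2 * rho_sd^2))
  z <- matrix(rnorm(n * n), n, n)
  tex <- Re(fft(fft(z) * H, inverse = TRUE)) / (n * n)
  tex / sd(tex)
}

# signed DFT sample frequencies in cycles/pixel, in R's fft index order
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

phantom_shepp_logan <- function(n) {
  # modified (high-contrast) Shepp-Logan ellipse table:
  # intensity, semi-axes a, b, centre x0, y0, rotation phi (degrees)
  e <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(ax, n, n)
  Y <- matrix(ax, n, n, byrow = TRUE)
  u <- matrix(0, n, n)
  for (i in seq_len(nrow(e))) {
    phi <- e[i, 6] * pi / 180
    xr <- cos(phi) * (X - e[i, 4]) + sin(phi) * (Y - e[i, 5])
    yr <- -sin(phi) * (X - e[i, 4]) + cos(phi) * (Y - e[i, 5])
    inside <- (xr / e[i, 2])^2 + (yr / e[i, 3])^2 <= 1
    u[inside] <- u[inside] + e[i, 1]
  }
  u <- pmin(pmax(u, 0), 1)
  attr(u, "meta") <- sprintf("shepp_logan phantom, n=%d", n)
  u
}
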
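# shared internal helpers: argument checks, seeded evaluation, padding,
# small separable / 2-D convolutions with mirror (symmetric) boundaries

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_image <- function(u, min_dim = 1L) {
  stop_if(!is.matrix(u) || !is.numeric(u), "image must be a numeric matrix")
  stop_if(any(!is.finite(u)), "image contains non-finite values")
  stop_if(nrow(u) < min_dim || ncol(u) < min_dim,
          sprintf("image must be at least %d x %d", min_dim, min_dim))
  invisible(u)
}

check_same_shape <- function(a, b) {
  stop_if(!identical(dim(a), dim(b)), "shape mismatch between images")
  invisible(NULL)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  stop_if(!is.numeric(seed) || length(seed) != 1L, "seed must be a single number")
  withr::with_seed(as.integer(seed), code)
}

# mirror ("symmetric") padding indices for length n and pad p; the edge sample
# is repeated, matching scipy's 'symmetric' mode: [p..1, 1..n, n..n-p+1]
mirror_idx <- function(n, p) {
  stop_if(p >= n, "padding exceeds image size")
  c(rev(seq_len(p)), seq_len(n), seq(n, by = -1L, length.out = p))
}

pad_mirror <- function(x, p) {
  if (p == 0L) return(x)
  x[mirror_idx(nrow(x), p), mirror_idx(ncol(x), p), drop = FALSE]
}

# separable 2-D convolution with a symmetric odd-length kernel pair and
# mirror boundaries; kernels are applied as correlation (they are symmetric
# wherever this matters: Gaussian windows and patch kernels)
conv_sep <- function(x, kx, ky = kx) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- x[mirror_idx(n, rx), , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(kx))
    out <- out + kx[t] * xp[seq_len(n) + (t - 1L), , drop = FALSE]
  outp <- out[, mirror_idx(m, ry), drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(ky))
    out <- out + ky[t] * outp[, seq_len(m) + (t - 1L), drop = FALSE]
  out
}

# separable correlation returning only the valid inner region (input padded
# by the kernel radius on each side); used where the padding is controlled
# by the caller, e.g. exact patch distances on a mirror-padded grid
conv_sep_valid <- function(x, kx, ky = kx) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  n <- nrow(x) - 2L * rx
  m <- ncol(x) - 2L * ry
  out <- matrix(0, n, ncol(x))
  for (t in seq_along(kx))
    out <- out + kx[t] * x[seq_len(n) + (t - 1L), , drop = FALSE]
  res <- matrix(0, n, m)
  for (t in seq_along(ky))
    res <- res + ky[t] * out[, seq_len(m) + (t - 1L), drop = FALSE]
  res
}

# full 2-D convolution with a small (odd-sized) stencil, mirror boundaries;
# `kernel` is applied as a convolution (flipped), matching the usual
# definition of Sobel/Scharr derivative stencils
conv2_mirror <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- pad_mirror(x, max(kr, kc))
  p <- max(kr, kc)
  out <- matrix(0, n, m)
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      if (kernel[a, b] == 0) next
      dr <- kr + 1L - a   # convolution: kernel index flipped
      dc <- kc + 1L - b
      out <- out + kernel[a, b] *
        xp[p + seq_len(n) + dr, p + seq_len(m) + dc, drop = FALSE]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma, radius = NULL) {
  radius <- radius %||% max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# accumulate per-edge values onto pixels: out[p] = sum(vals[idx == p])
edge_accumulate <- function(vals, idx, npix) {
  out <- numeric(npix)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}
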
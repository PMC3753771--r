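#' Variable-density random Cartesian undersampling mask
#'
#' Draws a k-space sampling pattern with more samples at low spatial
#' frequencies, the standard compressed-sensing MRI scheme. A central
#' low-frequency disk covering `center_fraction` of all points is always
#' fully sampled (as is the DC point), and the remaining points are drawn
#' without replacement with probability proportional to
#' `(1 - r)^decay`, where `r` is distance from DC normalized by the Nyquist
#' radius. The total number of selected points is exactly
#' `round(ratio * size^2)`.
#'
#' The mask is laid out in unshifted DFT order (DC at element `[1, 1]`),
#' matching [stats::fft()] and [forward_measure()].
#'
#' @param size side length of the (square) k-space grid.
#' @param ratio fraction of k-space points to acquire, in (0, 1].
#' @param decay exponent of the radial density law; larger values
#'   concentrate samples at low frequencies. Default 6.
#' @param center_fraction fraction of all points inside the fully sampled
#'   central disk; must be smaller than `ratio`. Default 0.04.
#' @param seed integer seed; masks are reproducible given the seed.
#' @return a logical `size` x `size` matrix of class `"sampling_mask"` with
#'   attributes `ratio`, `decay`, `center_fraction`, `seed`.
#' @examples
#' m <- make_vardens_mask(64, 0.2, seed = 1)
#' sum(m)  # exactly round(0.2 * 64^2)
#' @export
make_vardens_mask <- function(size, ratio, decay = 6, center_fraction = 0.04,
                              seed = 0L) {
  stop_if(!is.numeric(size) || size < 8, "size must be >= 8")
  stop_if(!(ratio > 0 && ratio <= 1), "ratio must be in (0, 1]")
  stop_if(decay <= 0, "decay must be positive")
  stop_if(center_fraction < 0 || center_fraction >= ratio,
          "center_fraction must be in [0, ratio)")
  size <- as.integer(size)
  total <- size * size
  k <- round(ratio * total)

  f <- fft_freq(size) * size          # signed integer frequencies
  D <- sqrt(outer(f^2, f^2, "+"))     # distance from DC in grid units
  r <- D / (size / 2)                 # 1 at the Nyquist frequency

  # fully sampled central disk of area center_fraction * total
  rad <- sqrt(center_fraction * total / pi)
  forced <- D <= rad
  forced[1, 1] <- TRUE                # DC always acquired
  n_forced <- sum(forced)
  stop_if(n_forced > k,
          "central disk exceeds the sampling budget; lower center_fraction")

  sel <- forced
  n_rest <- k - n_forced
  if (n_rest > 0) {
    cand <- which(!forced)
    prob <- pmax(1 - r[cand], 0)^decay + 1e-12
    picked <- with_seed(seed, sample(cand, n_rest, prob = prob))
    sel[picked] <- TRUE
  }
  structure(sel, class = c("sampling_mask", "matrix"),
            ratio = ratio, decay = decay,
            center_fraction = center_fraction, seed = as.integer(seed))
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d x %d, %d/%d points (%.1f%%), seed %d\n",
              nrow(x), ncol(x), sum(x), length(x),
              100 * sum(x) / length(x), attr(x, "seed")))
  invisible(x)
}

#' Fully sampled mask
#'
#' Convenience constructor for the complete Cartesian grid (ratio 1).
#'
#' @param size side length of the square k-space grid.
#' @return a `"sampling_mask"` with every point selected.
#' @export
full_mask <- function(size) {
  structure(matrix(TRUE, size, size), class = c("sampling_mask", "matrix"),
            ratio = 1, decay = NA_real_, center_fraction = 0, seed = 0L)
}

mask_ratio <- function(mask) sum(mask) / length(mask)
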
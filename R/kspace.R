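# unitary 2-D DFT pair: with the 1/sqrt(N) normalization on both directions
# the forward map and its inverse are adjoint without scale factors, and the
# diagonal of K^T K for a partial-Fourier K equals the sampling ratio
fft2u <- function(x) as_plain(fft(x) / sqrt(length(x)))
ifft2u <- function(X) as_plain(fft(X, inverse = TRUE) / sqrt(length(X)))

# drop any carried-over attributes (phantom labels etc.), keep the shape
as_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Partial-Fourier measurement of an image
#'
#' Applies the compressed-sensing MRI forward model `v = P F u`: a unitary
#' 2-D discrete Fourier transform followed by restriction to the sampling
#' mask. Entries outside the mask are exactly zero.
#'
#' @param u real image matrix.
#' @param mask a [make_vardens_mask()] / [full_mask()] sampling mask of the
#'   same shape.
#' @return an object of class `"kspace_meas"`: a list with complex matrix
#'   `values` (zero off the mask), the `mask`, and noise bookkeeping fields
#'   `noise_model` (`"none"`, `"gaussian"` or `"rician"`) and `noise_level`.
#' @examples
#' u <- make_phantom("piecewise", 32)
#' m <- forward_measure(u, full_mask(32))
#' @export
forward_measure <- function(u, mask) {
  check_image(u, min_dim = 8L)
  check_same_shape(u, mask)
  v <- fft2u(u)
  v[!mask] <- 0 + 0i
  new_kspace(v, mask, "none", 0)
}

new_kspace <- function(values, mask, noise_model, noise_level) {
  structure(list(values = values, mask = mask,
                 noise_model = noise_model, noise_level = noise_level),
            class = "kspace_meas")
}

#' @export
print.kspace_meas <- function(x, ...) {
  cat(sprintf("<kspace_meas> %d x %d, %.1f%% sampled, noise: %s (level %g)\n",
              nrow(x$values), ncol(x$values), 100 * mask_ratio(x$mask),
              x$noise_model, x$noise_level))
  invisible(x)
}

#' Add measurement noise to k-space data
#'
#' Two noise models are supported:
#'
#' * `"gaussian"` — i.i.d. complex Gaussian noise with standard deviation
#'   `level` per real/imaginary component, added on the acquired (masked)
#'   entries only. This models receiver noise in the raw k-space samples.
#' * `"rician"` — magnitude-image noise, as arises in magnitude MRI: the
#'   image-domain signal is corrupted via the two-channel construction
#'   `u_noisy = sqrt((u + n1)^2 + n2^2)` with `n1, n2 ~ N(0, (level * max(u))^2)`,
#'   and the result is re-measured through the mask. By default `u` is the
#'   measurement's image-domain representation (the zero-filled inverse);
#'   pass the ground-truth image via `image` to corrupt the true signal
#'   before encoding, which is the physical order of events.
#'
#' `level = 0` returns the input unchanged.
#'
#' @param m a `"kspace_meas"` object.
#' @param model `"gaussian"` or `"rician"`.
#' @param level noise level: component standard deviation for Gaussian;
#'   fraction of the maximum image intensity for Rician (e.g. 0.05 = "5%").
#' @param seed integer seed for reproducible noise.
#' @param image optional real image used as the Rician corruption target
#'   (ignored for Gaussian noise).
#' @return a new `"kspace_meas"` with the same mask.
#' @export
add_noise <- function(m, model = c("gaussian", "rician"), level, seed = 0L,
                      image = NULL) {
  model <- match.arg(model)
  stop_if(!inherits(m, "kspace_meas"), "m must be a kspace_meas")
  stop_if(level < 0, "noise level must be nonnegative")
  if (level == 0) return(m)
  v <- m$values
  mask <- m$mask
  if (model == "gaussian") {
    idx <- which(mask)
    noise <- with_seed(seed, complex(real = rnorm(length(idx), sd = level),
                                     imaginary = rnorm(length(idx), sd = level)))
    v[idx] <- v[idx] + noise
  } else {
    u <- if (is.null(image)) Re(ifft2u(v)) else image
    check_same_shape(u, mask)
    scale <- max(abs(u))
    if (scale == 0) scale <- 1   # reference scale for an all-zero image
    sdev <- level * scale
    u_noisy <- with_seed(seed, {
      n1 <- matrix(rnorm(length(u), sd = sdev), nrow(u))
      n2 <- matrix(rnorm(length(u), sd = sdev), nrow(u))
      sqrt((u + n1)^2 + n2^2)
    })
    v <- fft2u(u_noisy)
    v[!mask] <- 0 + 0i
  }
  new_kspace(v, mask, model, level)
}

#' Estimate the zero-filled reconstruction error from the data alone
#'
#' The zero-fill error is the inverse DFT of the unacquired k-space
#' coefficients (plus acquired noise). Because variable-density acquisition
#' selects coefficients at random within each radial frequency band, the
#' mean power of the *acquired* coefficients in a band is an unbiased
#' estimate of the power of the *unacquired* ones. Summing the estimated
#' missing power over bands and applying Parseval gives the per-pixel RMS
#' error of the zero-filled image — the natural filtering scale `h` for
#' patch weights built on that image ([compute_weights()]), since `h`
#' should match the noise level of the weight guide.
#'
#' @param m a `"kspace_meas"`.
#' @param n_bins number of radial frequency bins. Default 16.
#' @return estimated RMS error (intensity units); 0 for a fully sampled
#'   measurement.
#' @export
zero_fill_error_estimate <- function(m, n_bins = 16L) {
  stop_if(!inherits(m, "kspace_meas"), "m must be a kspace_meas")
  n <- nrow(m$values); mm <- ncol(m$values)
  fx <- fft_freq(n) * n; fy <- fft_freq(mm) * mm
  D <- sqrt(outer(fx^2, fy^2, "+"))
  r <- D / max(D)
  bins <- findInterval(as.vector(r), seq(0, 1, length.out = n_bins + 1),
                       rightmost.closed = TRUE)
  pw <- Mod(m$values)^2
  acq <- as.vector(m$mask)
  missing <- 0
  for (b in unique(bins)) {
    inb <- bins == b
    na <- sum(inb & acq); nu <- sum(inb & !acq)
    if (nu == 0 || na == 0) next
    missing <- missing + sum(pw[inb & acq]) / na * nu
  }
  sqrt(missing / length(m$values))
}

#' Zero-filled reconstruction
#'
#' Inverse unitary DFT of the measured k-space with unacquired coefficients
#' left at zero; the standard naive baseline and the solvers' initial
#' estimate. Returns the real part.
#'
#' @param m a `"kspace_meas"` object.
#' @return a real image matrix.
#' @export
zero_fill_recon <- function(m) {
  stop_if(!inherits(m, "kspace_meas"), "m must be a kspace_meas")
  Re(ifft2u(m$values))
}
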
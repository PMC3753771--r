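#' Signal-to-noise ratio of a reconstruction
#'
#' `SNR = 10 * log10( ||ref - mean(ref)|| / ||ref - rec|| )` with plain
#' (unsquared) Euclidean norms. Note this convention — the ratio of norms,
#' not of energies — differs from the common `20 * log10` definition by a
#' factor of 2 in dB. `Inf` is returned when `rec` equals `ref` exactly.
#'
#' @param ref reference image (must not be constant).
#' @param rec reconstructed image of the same shape.
#' @return SNR in dB.
#' @examples
#' u <- make_phantom("piecewise", 32)
#' snr(u, u + 0.01)
#' @export
snr <- function(ref, rec) {
  check_same_shape(ref, rec)
  num <- sqrt(sum((ref - mean(ref))^2))
  stop_if(num == 0, "reference image is constant; SNR undefined")
  den <- sqrt(sum((ref - rec)^2))
  if (den == 0) return(Inf)
  10 * log10(num / den)
}

#' Percent relative error
#'
#' `RE = ||rec - ref|| / ||ref|| * 100`.
#'
#' @inheritParams snr
#' @return relative error in percent.
#' @export
relative_error <- function(ref, rec) {
  check_same_shape(ref, rec)
  den <- sqrt(sum(ref^2))
  stop_if(den == 0, "reference image has zero norm")
  sqrt(sum((rec - ref)^2)) / den * 100
}

#' SSIM parameters
#'
#' @param K1,K2 small stabilizing constants; `C1 = (K1*L)^2`,
#'   `C2 = (K2*L)^2`. Defaults 0.01 and 0.03.
#' @param L dynamic range of the pixel values (255 for 8-bit images).
#' @param window_size,window_sigma size (odd) and standard deviation of the
#'   Gaussian weighting window. Defaults 11 and 1.5.
#' @return an `"ssim_params"` list.
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = 255,
                        window_size = 11L, window_sigma = 1.5) {
  stop_if(K1 <= 0 || K2 <= 0 || L <= 0, "K1, K2, L must be positive")
  stop_if(window_size %% 2 == 0, "window_size must be odd")
  structure(list(K1 = K1, K2 = K2, L = L,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma), class = "ssim_params")
}

#' Structural similarity index
#'
#' Mean over Gaussian-weighted local windows of
#' `(2 mux muy + C1)(2 sxy + C2) / ((mux^2 + muy^2 + C1)(sx^2 + sy^2 + C2))`.
#' Inputs are expected on the dynamic range `p$L` (use
#' [evaluate_pair()] for images on \[0, 1\], which rescales by 255). Local
#' statistics use mirror boundary padding.
#'
#' @param ref,rec images of the same shape on the dynamic range `p$L`.
#' @param p an [ssim_params()].
#' @return a single number in \[-1, 1\].
#' @export
ssim <- function(ref, rec, p = ssim_params()) {
  check_same_shape(ref, rec)
  stop_if(p$window_size > min(dim(ref)), "window larger than image")
  rad <- (p$window_size - 1L) %/% 2L
  k <- dnorm(seq(-rad, rad), sd = p$window_sigma)
  k <- k / sum(k)
  C1 <- (p$K1 * p$L)^2
  C2 <- (p$K2 * p$L)^2
  mu1 <- conv_sep(ref, k); mu2 <- conv_sep(rec, k)
  s11 <- conv_sep(ref * ref, k) - mu1^2
  s22 <- conv_sep(rec * rec, k) - mu2^2
  s12 <- conv_sep(ref * rec, k) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(map)
}

#' Evaluate a reconstruction with all four quality metrics
#'
#' Computes SNR (dB), relative error (%), SSIM and FSIM for a
#' reference/reconstruction pair. Images nominally on \[0, 1\] are rescaled
#' by 255 for SSIM and FSIM so that the 8-bit constants apply.
#'
#' @inheritParams snr
#' @param ssim_p an [ssim_params()].
#' @param fsim_p an [fsim_params()].
#' @return a one-row data frame with columns `snr_db`, `re_pct`, `ssim`,
#'   `fsim`.
#' @export
evaluate_pair <- function(ref, rec, ssim_p = ssim_params(),
                          fsim_p = fsim_params()) {
  data.frame(snr_db = snr(ref, rec),
             re_pct = relative_error(ref, rec),
             ssim = ssim(255 * ref, 255 * rec, ssim_p),
             fsim = fsim(255 * ref, 255 * rec, fsim_p))
}
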
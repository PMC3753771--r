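# Feature similarity index (FSIM) and its two feature maps: log-Gabor
# phase congruency (the primary, dimensionless structure measure) and the
# gradient magnitude.

#' FSIM parameters
#'
#' @param T1 stabilizing constant of the phase-congruency similarity term
#'   (dimensionless PC scale). Default 0.85.
#' @param T2 stabilizing constant of the gradient-magnitude term, on the
#'   8-bit intensity scale. Default 160.
#' @param alpha,beta exponents weighting the PC and GM similarity maps.
#'   Default 1 and 1.
#' @param n_scales,n_orient number of log-Gabor filter scales and
#'   orientations. Defaults 4 and 4.
#' @param min_wavelength wavelength (pixels) of the smallest-scale filter.
#'   Default 6.
#' @param mult wavelength scaling factor between successive scales.
#'   Default 2.
#' @param sigma_onf ratio defining the radial (log-frequency) bandwidth of
#'   each filter. Default 0.5978.
#' @param noise_k number of noise-energy standard deviations above the
#'   estimated noise mean used as the phase-congruency noise threshold;
#'   set to a negative value to disable compensation. Default 2.
#' @return an `"fsim_params"` list.
#' @export
fsim_params <- function(T1 = 0.85, T2 = 160, alpha = 1, beta = 1,
                        n_scales = 4L, n_orient = 4L, min_wavelength = 6,
                        mult = 2, sigma_onf = 0.5978, noise_k = 2) {
  stop_if(T1 <= 0 || T2 <= 0, "T1 and T2 must be positive")
  structure(list(T1 = T1, T2 = T2, alpha = alpha, beta = beta,
                 n_scales = as.integer(n_scales),
                 n_orient = as.integer(n_orient),
                 min_wavelength = min_wavelength, mult = mult,
                 sigma_onf = sigma_onf, noise_k = noise_k),
            class = "fsim_params")
}

# log-Gabor filter bank in the frequency domain (unshifted DFT order);
# returns a list of n_orient lists of n_scales real filter matrices, plus
# the angular spread used
loggabor_bank <- function(dims, p) {
  n <- dims[1]; m <- dims[2]
  fx <- fft_freq(n); fy <- fft_freq(m)
  FX <- matrix(fx, n, m)
  FY <- matrix(fy, n, m, byrow = TRUE)
  R <- sqrt(FX^2 + FY^2)
  R[1, 1] <- 1   # avoid log(0); DC is zeroed below
  theta <- atan2(-FY, FX)
  lp <- 1 / (1 + (R / 0.45)^30)   # low-pass keeps filters inside Nyquist
  radial <- vector("list", p$n_scales)
  for (s in seq_len(p$n_scales)) {
    f0 <- 1 / (p$min_wavelength * p$mult^(s - 1))
    g <- exp(-(log(R / f0))^2 / (2 * log(p$sigma_onf)^2)) * lp
    g[1, 1] <- 0
    radial[[s]] <- g
  }
  theta_sigma <- pi / p$n_orient / 1.2
  bank <- vector("list", p$n_orient)
  for (o in seq_len(p$n_orient)) {
    ang0 <- (o - 1) * pi / p$n_orient
    ds <- sin(theta) * cos(ang0) - cos(theta) * sin(ang0)
    dc <- cos(theta) * cos(ang0) + sin(theta) * sin(ang0)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    bank[[o]] <- lapply(radial, function(g) g * spread)
  }
  bank
}

#' Phase congruency map
#'
#' Computes the standard multi-scale, multi-orientation log-Gabor phase
#' congruency: per orientation, quadrature filter responses are summed over
#' scales, local energy is measured against the summed response amplitude,
#' and an automatic noise-energy threshold (estimated from the
#' smallest-scale amplitude distribution) is subtracted. The map is
#' dimensionless, lies in \[0, 1\], and is exactly invariant to affine
#' intensity rescaling of the input (positive gain; the DC offset is
#' discarded by the filters).
#'
#' @param img real image matrix, at least 32 x 32 so the filter bank is
#'   meaningfully supported.
#' @param p an [fsim_params()].
#' @return a nonnegative matrix of the same shape.
#' @export
phase_congruency <- function(img, p = fsim_params()) {
  check_image(img)
  stop_if(min(dim(img)) < 32, "image too small for the log-Gabor filter bank")
  bank <- loggabor_bank(dim(img), p)
  IMG <- fft(img)
  npts <- length(img)
  eps <- .Machine$double.eps
  energy_all <- matrix(0, nrow(img), ncol(img))
  an_all <- matrix(0, nrow(img), ncol(img))
  for (o in seq_len(p$n_orient)) {
    sumE <- sumO <- sumAn <- matrix(0, nrow(img), ncol(img))
    tau <- NULL
    for (s in seq_len(p$n_scales)) {
      eo <- fft(IMG * bank[[o]][[s]], inverse = TRUE) / npts
      e <- Re(eo); odd <- Im(eo)
      an <- sqrt(e^2 + odd^2)
      sumE <- sumE + e
      sumO <- sumO + odd
      sumAn <- sumAn + an
      if (s == 1) tau <- median(an) / sqrt(log(4))
    }
    xenergy <- sqrt(sumE^2 + sumO^2) + eps
    mean_e <- sumE / xenergy
    mean_o <- sumO / xenergy
    energy <- matrix(0, nrow(img), ncol(img))
    for (s in seq_len(p$n_scales)) {
      eo <- fft(IMG * bank[[o]][[s]], inverse = TRUE) / npts
      e <- Re(eo); odd <- Im(eo)
      energy <- energy + e * mean_e + odd * mean_o - abs(e * mean_o - odd * mean_e)
    }
    if (p$noise_k >= 0) {
      # Rayleigh-based noise-energy estimate from the smallest scale
      total_tau <- tau * (1 - (1 / p$mult)^p$n_scales) / (1 - 1 / p$mult)
      noise_mean <- total_tau * sqrt(pi / 2)
      noise_sigma <- total_tau * sqrt((4 - pi) / 2)
      energy <- pmax(energy - (noise_mean + p$noise_k * noise_sigma), 0)
    } else {
      energy <- pmax(energy, 0)
    }
    energy_all <- energy_all + energy
    an_all <- an_all + sumAn
  }
  pc <- energy_all / (an_all + eps)
  pmin(pmax(pc, 0), 1)
}

#' Gradient magnitude map
#'
#' `sqrt(Gx^2 + Gy^2)` with a 3 x 3 derivative stencil (Scharr by default)
#' and mirror boundary handling.
#'
#' @param img real image matrix.
#' @param operator `"scharr"`, `"sobel"` or `"prewitt"`.
#' @return a nonnegative matrix of the same shape.
#' @export
gradient_magnitude <- function(img, operator = c("scharr", "sobel", "prewitt")) {
  operator <- match.arg(operator)
  check_image(img)
  kx <- switch(operator,
    scharr  = matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, byrow = TRUE) / 16,
    sobel   = matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, byrow = TRUE) / 4,
    prewitt = matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, byrow = TRUE) / 3)
  gx <- conv2_mirror(img, kx)
  gy <- conv2_mirror(img, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index
#'
#' Pools the phase-congruency similarity
#' `S_PC = (2 PC1 PC2 + T1) / (PC1^2 + PC2^2 + T1)` and the
#' gradient-magnitude similarity
#' `S_G = (2 G1 G2 + T2) / (G1^2 + G2^2 + T2)` into
#' `S_L = S_PC^alpha * S_G^beta`, weighted by the maximal phase congruency:
#' `FSIM = sum(S_L * PCm) / sum(PCm)` with `PCm = max(PC1, PC2)`. Inputs are
#' expected on the 8-bit dynamic range (see [evaluate_pair()] for \[0, 1\]
#' images).
#'
#' @param ref,rec images of the same shape on the 0-255 scale.
#' @param p an [fsim_params()].
#' @return a single number in \[0, 1\].
#' @export
fsim <- function(ref, rec, p = fsim_params()) {
  check_same_shape(ref, rec)
  pc1 <- phase_congruency(ref, p)
  pc2 <- phase_congruency(rec, p)
  g1 <- gradient_magnitude(ref)
  g2 <- gradient_magnitude(rec)
  s_l <- fsim_pool_map(pc1, pc2, g1, g2, p)
  pcm <- pmax(pc1, pc2)
  fsim_pool(s_l, pcm)
}

# similarity map S_L from precomputed feature maps
fsim_pool_map <- function(pc1, pc2, g1, g2, p) {
  s_pc <- (2 * pc1 * pc2 + p$T1) / (pc1^2 + pc2^2 + p$T1)
  s_g <- (2 * g1 * g2 + p$T2) / (g1^2 + g2^2 + p$T2)
  s_pc^p$alpha * s_g^p$beta
}

# PC-weighted pooling of a similarity map (exposed for pooling diagnostics)
fsim_pool <- function(s_l, pcm) {
  w <- sum(pcm)
  if (w == 0) return(mean(s_l))   # no structure anywhere: unweighted mean
  sum(s_l * pcm) / w
}
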
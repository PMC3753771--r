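# nltvrecon

Compressed-sensing MRI reconstruction with **nonlocal total variation
(NLTV)** regularization, solved by **split Bregman** iteration, together
with the full simulation and evaluation loop needed to study it: synthetic
phantoms, variable-density k-space undersampling, Gaussian/Rician noise, an
isotropic-TV split Bregman baseline, and the SNR / RE / SSIM / FSIM image
quality metrics.

The package is aimed at researchers in MR image reconstruction and
biological image analysis who want a transparent, fully tested reference
implementation of NLTV-regularized compressed sensing — every operator
(nonlocal gradient, divergence, Laplacian, shrinkage, the Bregman refresh)
is exposed and unit-tested against brute-force oracles.

## The model

MRI acquires Fourier coefficients of the image. With an undersampled
acquisition `v = P F u + n` (`F` the unitary 2-D DFT, `P` a row selector
keeping ~20% of k-space, `n` noise), the image is recovered by

```
min_u  ||∇_NL u||_1  +  (μ/2) ||P F u − v^k||²,
v^{k+1} = v^k + v − P F u^{k+1},
```

where the nonlocal gradient couples each pixel `i` to the pixels `j` in a
search window whose 5×5 patches look alike:

```
(∇_NL u)_ij = (u_j − u_i) √w_ij,      w_ij = exp(−G_σ*||patch_i − patch_j||² / h²).
```

Unlike local TV, which flattens texture along with noise, the NLTV penalty
averages along self-similar structures and preserves them. The L1 problem
is split: an auxiliary edge field `d ≈ ∇_NL u` is updated by closed-form
groupwise shrinkage, a Bregman edge variable `b` absorbs the splitting
error, and the image update solves
`(γ ∇_NLᵀ∇_NL + μ KᵀK) u = μ Kᵀv^k + γ ∇_NLᵀ(d − b)` with a few
diagonally preconditioned relaxation sweeps driven by exact FFT residuals.

## Worked example

```r
library(nltvrecon)

u    <- make_phantom("textured", 64, seed = 1)        # ground truth in [0,1]
mask <- make_vardens_mask(64, ratio = 0.2, seed = 1)  # 819 of 4096 points
v    <- add_noise(forward_measure(u, mask), "gaussian", 0.01, seed = 2)

zf   <- zero_fill_recon(v)                            # naive baseline
g    <- compute_weights(zf, h = zero_fill_error_estimate(v))
fit  <- reconstruct_nltv(v, g, solver_params(), ref = u)

evaluate_pair(u, zf)
#>  snr_db re_pct   ssim   fsim
#>   7.072  14.72 0.7681 0.7545
evaluate_pair(u, fit$image)
#>  snr_db re_pct   ssim   fsim
#>   11.99  4.746 0.9745 0.9696
```

Reading: zero-filling leaves 14.7% relative error from aliasing; 30 outer
split Bregman iterations with the patch-similarity graph (here ~54k edges,
`h` set to the estimated zero-fill error 0.059) cut it to 4.7% and raise the
norm-ratio SNR from 7.1 dB to 12.0 dB. `fit$history` tracks the objective,
relative change and SNR per sweep. The TV baseline (`reconstruct_tv`) lands
in between — it removes aliasing but smooths the texture the NLTV weights
preserve.

A multi-seed comparison in one call:

```r
cmp <- compare_methods(experiment_config(), mask_seeds = 1:5)
cmp$summary
#>     method    snr_db    re_pct      ssim      fsim n_seeds
#>  zero_fill  7.083088 14.681566 0.7790045 0.7576253       5
#>      sb_tv 10.338265  6.939915 0.9584537 0.9527434       5
#>       nltv 11.800915  4.961170 0.9733534 0.9670869       5
```

The same pipeline is scriptable from a shell via `inst/cli/nltvrecon`
(subcommands `phantom`, `mask`, `measure`, `recon`, `evaluate`, `compare`,
configured by a YAML file; see `?experiment_config`).

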
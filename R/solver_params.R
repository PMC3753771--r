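#' Parameters for the NLTV split Bregman solver
#'
#' @param mu data-fidelity weight (balance between the k-space residual and
#'   the NLTV penalty). Default 100, tuned for unit-intensity images.
#' @param gamma splitting weight of the quadratic coupling between the
#'   auxiliary edge variable and the nonlocal gradient; `1/gamma` is the
#'   shrinkage threshold. Default 10.
#' @param n_outer outer Bregman data-refresh iterations. Default 30.
#' @param n_inner inner u/d/b sweeps per outer step. Default 1.
#' @param gs_sweeps relaxation sweeps of the u-subproblem per inner sweep.
#'   Default 4.
#' @param tol early-stopping threshold on the relative change of `u`
#'   between outer iterations. Default 1e-4.
#' @param sweep_type `"gauss_seidel"` (red/black two-colour sweeps, the
#'   default) or `"jacobi"` (simultaneous update); both use the exact FFT
#'   residual, the exact diagonal, and an exact line step, so each sweep
#'   decreases the quadratic u-subproblem.
#' @param seed recorded for provenance; the solver itself is deterministic.
#' @return a `"solver_params"` list.
#' @export
solver_params <- function(mu = 100, gamma = 10, n_outer = 30L, n_inner = 1L,
                          gs_sweeps = 4L, tol = 1e-4,
                          sweep_type = c("gauss_seidel", "jacobi"),
                          seed = 0L) {
  sweep_type <- match.arg(sweep_type)
  stop_if(mu <= 0 || gamma <= 0, "mu and gamma must be positive")
  stop_if(n_outer < 1 || n_inner < 1 || gs_sweeps < 1,
          "iteration counts must be positive")
  stop_if(tol < 0, "tol must be nonnegative")
  structure(list(mu = mu, gamma = gamma, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 gs_sweeps = as.integer(gs_sweeps), tol = tol,
                 sweep_type = sweep_type, seed = as.integer(seed)),
            class = "solver_params")
}

#' Parameters for the isotropic-TV split Bregman baseline
#'
#' Same roles as [solver_params()]; `lambda_split` plays the part of
#' `gamma` (the splitting weight, with `1/lambda_split` the shrinkage
#' threshold).
#'
#' @inheritParams solver_params
#' @param lambda_split splitting weight of the TV baseline. Default 10.
#' @return a `"tv_params"` list.
#' @export
tv_params <- function(mu = 100, lambda_split = 10, n_outer = 30L,
                      n_inner = 1L, gs_sweeps = 4L, tol = 1e-4,
                      sweep_type = c("gauss_seidel", "jacobi")) {
  sweep_type <- match.arg(sweep_type)
  stop_if(mu <= 0 || lambda_split <= 0, "mu and lambda_split must be positive")
  stop_if(n_outer < 1 || n_inner < 1 || gs_sweeps < 1,
          "iteration counts must be positive")
  stop_if(tol < 0, "tol must be nonnegative")
  structure(list(mu = mu, lambda_split = lambda_split,
                 n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 gs_sweeps = as.integer(gs_sweeps), tol = tol,
                 sweep_type = sweep_type),
            class = "tv_params")
}

#' Soft-thresholding (shrinkage) operator
#'
#' The closed-form proximal operator of the L1 norm:
#' `shrink(x, lam) = (x / |x|) * max(|x| - lam, 0)`, with 0 returned at
#' `x = 0`. Vectorized over `x`.
#'
#' @param x numeric vector, matrix, or edge field.
#' @param lam nonnegative threshold.
#' @return same shape as `x`.
#' @examples
#' shrink(c(-2, 0.3, 2), 0.5)
#' @export
shrink <- function(x, lam) {
  stop_if(lam < 0, "lam must be nonnegative")
  sign(x) * pmax(abs(x) - lam, 0)
}
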
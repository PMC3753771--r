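# Isotropic-TV split Bregman baseline.
#
# Same outer/inner loop structure as the NLTV solver, but with the local
# forward-difference gradient (two directions, Neumann boundary: the last
# difference in each direction is zero) and isotropic two-component
# shrinkage. Kept as an independent dense implementation so that it can
# cross-validate the NLTV solver on the unit forward-difference graph.

# forward differences; q arrays carry a zero in the last row/column
dx_f <- function(u) rbind(u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
dy_f <- function(u) cbind(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)

# exact adjoints of the forward differences above
dx_t <- function(q) {
  n <- nrow(q)
  q[n, ] <- 0
  rbind(0, q[-n, , drop = FALSE]) - rbind(q[-n, , drop = FALSE], 0)
}
dy_t <- function(q) {
  m <- ncol(q)
  q[, m] <- 0
  cbind(0, q[, -m, drop = FALSE]) - cbind(q[, -m, drop = FALSE], 0)
}

tv_A <- function(x, mask, mu, lam) {
  lam * (dx_t(dx_f(x)) + dy_t(dy_f(x))) + mu * ktk_apply(x, mask)
}

# diagonal of Dx^T Dx + Dy^T Dy: 2 per direction in the interior, 1 at the
# first and last index of that direction
tv_diag <- function(n, m, mask, mu, lam) {
  dr <- (row(matrix(0, n, m)) > 1) + (row(matrix(0, n, m)) < n)
  dc <- (col(matrix(0, n, m)) > 1) + (col(matrix(0, n, m)) < m)
  mu * mask_ratio(mask) + lam * (dr + dc)
}

#' Isotropic-TV split Bregman reconstruction (baseline)
#'
#' The classical split Bregman compressed-sensing reconstruction with an
#' isotropic total-variation penalty over local forward differences. Shares
#' the loop structure and the outer Bregman data refresh with
#' [reconstruct_nltv()] and serves as its local-regularizer baseline.
#'
#' @param v a `"kspace_meas"`.
#' @param params a [tv_params()].
#' @param ref optional ground-truth image for per-iteration SNR.
#' @return a list with `image` and `history` (same layout as
#'   [reconstruct_nltv()]).
#' @export
reconstruct_tv <- function(v, params = tv_params(), ref = NULL) {
  stop_if(!inherits(v, "kspace_meas"), "v must be a kspace_meas")
  mu <- params$mu; lam <- params$lambda_split
  mask <- v$mask
  u <- zero_fill_recon(v)
  if (any(!is.finite(u)))
    stop("solver diverged at outer iteration 0: non-finite initialization",
         call. = FALSE)
  n <- nrow(u); m <- ncol(u)
  dx <- dy <- bx <- by <- matrix(0, n, m)
  vk <- v$values
  diagv <- tv_diag(n, m, mask, mu, lam)
  chk <- (row(u) + col(u)) %% 2
  colors <- if (params$sweep_type == "gauss_seidel")
    list(chk == 0, chk == 1) else list(matrix(TRUE, n, m))

  obj <- function() {
    sum(sqrt(dx^2 + dy^2)) +
      lam / 2 * sum((dx - dx_f(u) - bx)^2 + (dy - dy_f(u) - by)^2) +
      mu / 2 * sum(Mod(fft2u(u) * mask - vk)^2)
  }

  hist <- vector("list", params$n_outer * params$n_inner)
  hrow <- 0L
  for (k in seq_len(params$n_outer)) {
    u_prev <- u
    for (it in seq_len(params$n_inner)) {
      obj0 <- obj()
      rhs <- mu * Re(ifft2u(vk)) + lam * (dx_t(dx - bx) + dy_t(dy - by))
      r <- rhs - tv_A(u, mask, mu, lam)
      for (s in seq_len(params$gs_sweeps)) {
        for (cl in colors) {
          p <- (r / diagv) * cl
          Ap <- tv_A(p, mask, mu, lam)
          pAp <- sum(p * Ap)
          if (pAp <= 0) next
          alpha <- sum(r * p) / pAp
          u <- u + alpha * p
          r <- r - alpha * Ap
        }
      }
      if (any(!is.finite(u)))
        stop(sprintf("solver diverged at outer iteration %d", k), call. = FALSE)
      obj_u <- obj()
      sx <- dx_f(u) + bx
      sy <- dy_f(u) + by
      nrm <- sqrt(sx^2 + sy^2)
      fac <- ifelse(nrm > 0, pmax(nrm - 1 / lam, 0) / nrm, 0)
      dx <- sx * fac; dy <- sy * fac
      obj_d <- obj()                   # d minimized with b still frozen
      bx <- sx - dx; by <- sy - dy
      hrow <- hrow + 1L
      hist[[hrow]] <- data.frame(
        outer = k, inner = it, obj_start = obj0, obj_after_u = obj_u,
        obj_after_d = obj_d, rel_change = NA_real_,
        snr = if (is.null(ref)) NA_real_ else snr(ref, u))
    }
    vk <- vk + v$values - fft2u(u)
    vk[!mask] <- 0 + 0i
    rel <- sqrt(sum((u - u_prev)^2)) / max(sqrt(sum(u_prev^2)), .Machine$double.eps)
    hist[[hrow]]$rel_change <- rel
    if (rel < params$tol) break
  }
  list(image = u, history = do.call(rbind, hist[seq_len(hrow)]))
}
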
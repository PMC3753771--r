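#' Build a patch-similarity weight graph
#'
#' Computes nonlocal-means style weights
#' `w_ij = exp(-(G_sigma * ||patch_i - patch_j||^2) / h^2)`
#' between each pixel and the pixels in a surrounding search window, where
#' the squared patch difference is averaged with a normalized Gaussian patch
#' kernel of standard deviation `sigma_patch`. Per pixel, only the
#' `neighbors_kept` largest weights are retained; the result is then
#' symmetrized with `w <- max(w, t(w))`. Patches use mirror (symmetric)
#' boundary padding; neighbours whose centre falls outside the image are
#' dropped.
#'
#' The guide image is typically the zero-filled reconstruction of the noisy
#' data (the image-domain counterpart of the observed k-space samples).
#'
#' @param guide real image the weights are computed from.
#' @param patch_radius patch half-width (2 gives 5 x 5 patches, the default).
#' @param search_radius search-window half-width (5 gives 11 x 11 windows).
#' @param h filtering parameter; weights decay with patch distance over
#'   `h^2`. Commonly set to the noise standard deviation.
#' @param sigma_patch standard deviation (pixels) of the Gaussian patch
#'   kernel. Default 1.
#' @param neighbors_kept number of largest-weight neighbours retained per
#'   pixel before symmetrization. Default 10.
#' @return an `"nl_graph"`: a list with parallel edge vectors `i`, `j`, `w`
#'   (weights in (0, 1]), `sw = sqrt(w)`, the image `dim`, and the build
#'   parameters. Edges are stored in both directions (`w` symmetric).
#' @examples
#' g <- compute_weights(make_phantom("piecewise", 16), h = 0.1)
#' range(g$w)
#' @export
compute_weights <- function(guide, patch_radius = 2L, search_radius = 5L,
                            h, sigma_patch = 1, neighbors_kept = 10L) {
  check_image(guide, min_dim = 2L * patch_radius + 1L)
  stop_if(h <= 0, "h must be positive")
  stop_if(patch_radius < 1 || search_radius < 1, "radii must be >= 1")
  n <- nrow(guide); m <- ncol(guide); npix <- n * m

  kern <- gaussian_kernel_1d(sigma_patch, radius = patch_radius)
  offs <- expand.grid(dr = -search_radius:search_radius,
                      dc = -search_radius:search_radius)
  offs <- offs[offs$dr != 0 | offs$dc != 0, ]

  rows <- matrix(seq_len(n), n, m)
  cols <- matrix(seq_len(m), n, m, byrow = TRUE)

  n_off <- nrow(offs)
  Wc <- matrix(-Inf, npix, n_off)     # candidate weights (per offset column)
  Jc <- matrix(NA_integer_, npix, n_off)
  # distances are computed on the mirror-padded grid so that every patch —
  # including those of border pixels — is read from the same padded image;
  # this makes D(i, j) exactly symmetric and equal to the literal
  # Gaussian-weighted patch distance
  P <- as.integer(patch_radius); S <- as.integer(search_radius)
  gpp <- pad_mirror(guide, S + P)
  rsel <- (S + 1):(S + n + 2L * P)
  csel <- (S + 1):(S + m + 2L * P)
  for (t in seq_len(n_off)) {
    dr <- offs$dr[t]; dc <- offs$dc[t]
    d2 <- (gpp[rsel, csel, drop = FALSE] -
           gpp[rsel + dr, csel + dc, drop = FALSE])^2
    Dt <- conv_sep_valid(d2, kern)
    w <- exp(-Dt / h^2)
    jr <- rows + dr; jc <- cols + dc
    ok <- jr >= 1 & jr <= n & jc >= 1 & jc <= m
    jlin <- (pmin(pmax(jc, 1L), m) - 1L) * n + pmin(pmax(jr, 1L), n)
    Wc[, t] <- ifelse(ok, w, -Inf)
    Jc[, t] <- jlin
  }

  # per-pixel top-k selection by weight; out-of-bounds candidates carry -Inf
  # and are dropped after indexing
  k <- min(neighbors_kept, n_off)
  sel <- vapply(seq_len(npix),
                function(p) order(Wc[p, ], decreasing = TRUE)[seq_len(k)],
                FUN.VALUE = integer(k))
  ei <- rep(seq_len(npix), each = k)
  idx <- cbind(ei, as.vector(sel))
  ew <- Wc[idx]
  ej <- Jc[idx]
  keep <- is.finite(ew)
  ei <- ei[keep]; ej <- ej[keep]; ew <- ew[keep]

  new_nl_graph(ei, ej, ew, dim = c(n, m), symmetrize = TRUE,
               params = list(patch_radius = patch_radius,
                             search_radius = search_radius, h = h,
                             sigma_patch = sigma_patch,
                             neighbors_kept = neighbors_kept))
}

# assemble an nl_graph from raw directed edges; optionally take the
# symmetric closure with w = max(w_ij, w_ji); edges end up sorted by (i, j)
new_nl_graph <- function(i, j, w, dim, symmetrize, params = list()) {
  npix <- prod(dim)
  stop_if(any(i == j), "self-edges are not allowed")
  stop_if(any(w <= 0) || any(w > 1 + 1e-12), "weights must lie in (0, 1]")
  if (symmetrize) {
    i2 <- c(i, j); j2 <- c(j, i); w2 <- c(w, w)
    key <- (as.numeric(i2) - 1) * npix + as.numeric(j2)
    o <- order(key, -w2)
    first <- !duplicated(key[o])
    i <- i2[o][first]; j <- j2[o][first]; w <- pmin(w2[o][first], 1)
  } else {
    key <- (as.numeric(i) - 1) * npix + as.numeric(j)
    o <- order(key)
    i <- i[o]; j <- j[o]; w <- w[o]
  }
  structure(list(i = as.integer(i), j = as.integer(j), w = w, sw = sqrt(w),
                 dim = as.integer(dim), npix = as.integer(npix),
                 symmetric = symmetrize, params = params),
            class = "nl_graph")
}

#' @export
print.nl_graph <- function(x, ...) {
  cat(sprintf("<nl_graph> %d x %d image, %d directed edges (%s)\n",
              x$dim[1], x$dim[2], length(x$i),
              if (x$symmetric) "symmetric" else "directed"))
  invisible(x)
}

#' Unit-weight forward-difference graph
#'
#' The directed graph with unit-weight edges from each pixel to its +x and
#' +y neighbours. On this graph the nonlocal gradient norm is exactly the
#' isotropic discrete TV magnitude `sqrt(dx^2 + dy^2)` with forward
#' differences, which makes the NLTV solver coincide with the isotropic-TV
#' split Bregman baseline — the bridge used to validate both.
#'
#' @param dim integer vector `c(nrow, ncol)` (a single number is taken as a
#'   square size).
#' @return an `"nl_graph"` (directed; its weight matrix is symmetric in
#'   value but only forward edges are stored).
#' @export
tv_graph <- function(dim) {
  if (length(dim) == 1L) dim <- c(dim, dim)
  n <- dim[1]; m <- dim[2]
  rows <- matrix(seq_len(n), n, m)
  cols <- matrix(seq_len(m), n, m, byrow = TRUE)
  lin <- (cols - 1L) * n + rows
  down <- rows < n    # +x: next row
  right <- cols < m   # +y: next column
  i <- c(lin[down], lin[right])
  j <- c(lin[down] + 1L, lin[right] + n)
  new_nl_graph(i, j, rep(1, length(i)), dim = c(n, m), symmetrize = FALSE,
               params = list(kind = "tv_forward"))
}

#' Symmetric 4-neighbour unit graph
#'
#' Unit weights on all 4-connected pixel pairs, stored in both directions.
#' Mostly useful for operator tests (Laplacian identities, adjointness).
#'
#' @inheritParams tv_graph
#' @return a symmetric `"nl_graph"`.
#' @export
lattice_graph <- function(dim) {
  g <- tv_graph(dim)
  new_nl_graph(g$i, g$j, g$w, dim = g$dim, symmetrize = TRUE,
               params = list(kind = "lattice4"))
}

#' Serialize / read a weight graph as a sparse triplet file
#'
#' Writes the edge list as a three-column tab-separated file `(i, j, w)`
#' plus a JSON sidecar (`<path>.json`) holding the image dimensions and
#' build parameters.
#'
#' @param g an `"nl_graph"`.
#' @param path output path for the TSV edge list.
#' @return `save_graph` returns `path` invisibly; `load_graph` returns the
#'   reconstructed `"nl_graph"`.
#' @export
save_graph <- function(g, path) {
  stop_if(!inherits(g, "nl_graph"), "g must be an nl_graph")
  utils::write.table(data.frame(i = g$i, j = g$j, w = g$w), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(dim = g$dim, symmetric = g$symmetric,
                            params = g$params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- new_nl_graph(tab$i, tab$j, tab$w, dim = meta$dim,
                    symmetrize = FALSE, params = as.list(meta$params))
  g$symmetric <- isTRUE(meta$symmetric)
  g
}
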
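# Discrete nonlocal calculus on a weight graph.
#
# Edge fields are plain numeric vectors aligned with the graph's edge list
# (one value per stored directed edge). With the gradient defined through
# sqrt(w) per edge and the per-pixel norm summing w-weighted squared
# differences, the continuous definitions and the discrete norm are
# simultaneously satisfied and the divergence below is the exact negative
# adjoint of the gradient — for symmetric and for directed graphs alike.

#' Nonlocal gradient of an image
#'
#' Per stored edge `(i, j)`: `(grad u)_ij = (u_j - u_i) * sqrt(w_ij)`.
#'
#' @param u real image matrix matching the graph's dimensions.
#' @param g an `"nl_graph"`.
#' @return a numeric edge field (one value per edge of `g`).
#' @export
nl_gradient <- function(u, g) {
  check_graph_image(u, g)
  (u[g$j] - u[g$i]) * g$sw
}

#' Per-pixel nonlocal gradient magnitude
#'
#' Pixel `i` receives `sqrt(sum_j (u_j - u_i)^2 * w_ij)` over its outgoing
#' edges — the pointwise NLTV integrand. On the [tv_graph()] this equals the
#' isotropic forward-difference TV magnitude.
#'
#' @inheritParams nl_gradient
#' @return a nonnegative image matrix.
#' @export
nl_gradient_norm <- function(u, g) {
  check_graph_image(u, g)
  q2 <- (u[g$j] - u[g$i])^2 * g$w
  matrix(sqrt(edge_accumulate(q2, g$i, g$npix)), g$dim[1], g$dim[2])
}

#' Nonlocal divergence of an edge field
#'
#' The negative adjoint of [nl_gradient()]:
#' `(div q)_p = sum_{(p,j)} q_pj sqrt(w_pj) - sum_{(i,p)} q_ip sqrt(w_ip)`,
#' i.e. outgoing minus incoming flux. For a symmetric graph this reduces to
#' the familiar `sum_j (q_ij - q_ji) sqrt(w_ij)`. The identity
#' `<grad u, q> = -<u, div q>` holds to floating precision by construction.
#'
#' @param q numeric edge field aligned with `g`.
#' @param g an `"nl_graph"`.
#' @return a real image matrix.
#' @export
nl_divergence <- function(q, g) {
  stop_if(length(q) != length(g$i), "edge field does not match the graph")
  flux <- q * g$sw
  out <- edge_accumulate(flux, g$i, g$npix) -
         edge_accumulate(flux, g$j, g$npix)
  matrix(out, g$dim[1], g$dim[2])
}

#' Nonlocal (graph) Laplacian
#'
#' `(Lap u)_i = sum_j (u_j - u_i) * w_ij` over outgoing edges. For a
#' symmetric graph this equals `div(grad u) / 2`.
#'
#' @inheritParams nl_gradient
#' @return a real image matrix.
#' @export
nl_laplacian <- function(u, g) {
  check_graph_image(u, g)
  matrix(edge_accumulate((u[g$j] - u[g$i]) * g$w, g$i, g$npix),
         g$dim[1], g$dim[2])
}

# gradient transpose applied to an edge field: grad^T q = -div q
nl_grad_t <- function(q, g) -nl_divergence(q, g)

# per-pixel group norm of an edge field: n_i = sqrt(sum over outgoing q_ij^2)
nl_group_norm <- function(q, g) {
  sqrt(edge_accumulate(q^2, g$i, g$npix))
}

# diagonal of grad^T grad as a pixel vector: sum of w over outgoing plus
# incoming edges (2 * degree for a symmetric graph)
nl_gtg_diag <- function(g) {
  edge_accumulate(g$w, g$i, g$npix) + edge_accumulate(g$w, g$j, g$npix)
}

check_graph_image <- function(u, g) {
  stop_if(!inherits(g, "nl_graph"), "g must be an nl_graph")
  stop_if(!is.matrix(u) || !identical(dim(u), as.integer(g$dim)),
          "image shape does not match the graph")
  invisible(NULL)
}
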
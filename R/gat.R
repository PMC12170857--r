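# Multi-head graph attention layer with hand-derived gradients.
#
# Edges are directed index vectors (ei -> ej) including self-loops; the
# attention of node i over neighbour j is a softmax (over j in N(i)) of
# LeakyReLU(a_src . W h_i + a_dst . W h_j), i.e. the usual GAT scoring with
# the attention vector a split into its source and destination halves.

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope) slope + (1 - slope) * (x > 0)
elu <- function(x) pmax(x, 0) + exp(pmin(x, 0)) - 1
elu_grad <- function(x) exp(pmin(x, 0))

#' Initialize parameters of one multi-head GAT layer
#'
#' Weight matrices use Glorot-uniform initialization; attention vectors are
#' drawn small. Uses the current RNG state.
#'
#' @param d_in,d_out Input/output feature dimensions.
#' @param Q Number of attention heads.
#' @param slope LeakyReLU negative slope for attention logits.
#' @return A `gat_layer_params` list with per-head `W` (d_in x d_out) and
#'   attention vector halves `a_src`, `a_dst` (length d_out each; their
#'   concatenation is the conventional length-2*d_out attention vector).
#' @export
init_gat_layer <- function(d_in, d_out, Q = 3L, slope = 0.2) {
  lim <- sqrt(6 / (d_in + d_out))
  lima <- sqrt(6 / (2 * d_out + 1))
  structure(list(
    W = lapply(seq_len(Q), function(q)
      matrix(runif(d_in * d_out, -lim, lim), d_in, d_out)),
    a_src = lapply(seq_len(Q), function(q) runif(d_out, -lima, lima)),
    a_dst = lapply(seq_len(Q), function(q) runif(d_out, -lima, lima)),
    slope = slope, Q = Q, d_in = d_in, d_out = d_out
  ), class = "gat_layer_params")
}

# Directed edge index (both directions + self loops) from a unified_graph
# or adjacency matrix.
edge_index <- function(x) {
  if (inherits(x, "unified_graph")) {
    e <- x$edges; n <- x$n
    ei <- c(e$u, e$v, seq_len(n))
    ej <- c(e$v, e$u, seq_len(n))
  } else {
    if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
    A <- methods::as(methods::as(x, "generalMatrix"), "TsparseMatrix")
    n <- nrow(A)
    ei <- A@i + 1L; ej <- A@j + 1L
  }
  o <- order(ei, ej)
  list(ei = as.integer(ei[o]), ej = as.integer(ej[o]), n = n)
}

# internal forward with cache; h is n x d_in, edges from edge_index().
# All heads run through one stacked compiled kernel.
gat_fwd <- function(h, edges, params, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  n <- edges$n
  if (!all(seq_len(n) %in% edges$ei))
    stop("isolated node without self-loop", call. = FALSE)
  Wall <- do.call(cbind, params$W)
  asrc <- do.call(cbind, params$a_src)
  adst <- do.call(cbind, params$a_dst)
  fw <- cpp_gat_fwd(h, Wall, asrc, adst, edges$ei, edges$ej, params$slope,
                    activation == "elu", n)
  list(out = fw$out, Hall = fw$Hall, alpha = fw$alpha, raw = fw$raw,
       act_grad = fw$grad, Wall = Wall, asrc = asrc, adst = adst, h = h,
       edges = edges, params = params, activation = activation)
}

# backward: returns gradients for params and the layer input
gat_bwd <- function(dout, cache, need_dh = TRUE) {
  p <- cache$params; e <- cache$edges
  bw <- cpp_gat_bwd(dout, cache$act_grad %||% matrix(0, 0, 0),
                    cache$activation == "elu", cache$h, cache$Hall,
                    cache$alpha, cache$raw, cache$Wall, cache$asrc,
                    cache$adst, e$ei, e$ej, p$slope, need_dh, e$n)
  dd <- p$d_out
  idx <- function(q) ((q - 1L) * dd + 1L):(q * dd)
  list(W = lapply(seq_len(p$Q), function(q) bw$dWall[, idx(q), drop = FALSE]),
       a_src = lapply(seq_len(p$Q), function(q) bw$dasrc[, q]),
       a_dst = lapply(seq_len(p$Q), function(q) bw$dadst[, q]),
       dh = if (need_dh) bw$dh else NULL)
}

#' Forward pass of one multi-head graph attention layer
#'
#' Per head, attention coefficients over each neighbourhood (self-loop
#' included) are a softmax of LeakyReLU-scored pairs; the layer output is
#' the activation of the head-averaged attention-weighted neighbour sum.
#'
#' @param h Node features, n x d_in.
#' @param A Symmetric adjacency (sparse or dense) with self-loops; a node
#'   with no edge at all (not even a self-loop) is an error.
#' @param params A [init_gat_layer()] parameter set.
#' @param activation `"elu"` (default, hidden layers) or `"identity"`
#'   (moment heads).
#' @return n x d_out output matrix.
#' @export
gat_forward <- function(h, A, params, activation = "elu") {
  out <- gat_fwd(as.matrix(h), edge_index(A), params, activation)$out
  assert_finite(out, "gat layer output")
  out
}
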
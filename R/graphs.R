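#' Intra-slice spatial neighbour edges
#'
#' Links spatially adjacent spots within one slice, either by k-nearest
#' neighbours (symmetrized) or by a distance radius calibrated so the mean
#' degree falls in `target_degree`.
#'
#' @param coords Spots x 2 coordinate matrix (>= 2 spots).
#' @param mode `"knn"` or `"radius"`.
#' @param k Neighbours per spot in knn mode. Ties in distance are broken by
#'   lowest spot index.
#' @param target_degree Length-2 interval for the mean degree in radius
#'   mode (default `c(5, 6)`); ignored when `r` is given.
#' @param r Fixed radius (radius mode); if `NULL`, calibrated by bisection.
#' @return Two-column integer matrix of unordered edges (u < v), 1-based.
#' @export
build_intra_edges <- function(coords, mode = c("knn", "radius"), k = 6L,
                              target_degree = c(5, 6), r = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 spots", call. = FALSE)
  D <- as.matrix(dist(coords))
  if (all(D[upper.tri(D)] == 0))
    stop("all coordinates identical", call. = FALSE)
  if (mode == "knn") {
    k <- min(k, n - 1L)
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      ord <- order(D[i, -i], seq_len(n)[-i])  # tie-break: lowest index
      nb <- seq_len(n)[-i][ord[seq_len(k)]]
      cbind(i, nb)
    }))
  } else {
    if (is.null(r)) {
      du <- D[upper.tri(D)]
      lo <- min(du[du > 0]); hi <- max(du)
      mean_deg <- function(rr) 2 * sum(du <= rr) / n
      for (it in seq_len(100L)) {
        mid <- (lo + hi) / 2
        md <- mean_deg(mid)
        if (md < target_degree[1L]) lo <- mid
        else if (md > target_degree[2L]) hi <- mid
        else { r <- mid; break }
      }
      if (is.null(r)) {
        # degenerate layouts (e.g. exact regular grids) have discrete
        # distance rings and no radius lands in the band; take the largest
        # radius below the band and add edges from the next ring in
        # deterministic (u, v) order until the band is reached
        cand <- sort(unique(du))
        degs <- vapply(cand, mean_deg, 0)
        below <- which(degs < target_degree[1L])
        r <- if (length(below)) cand[max(below)] else cand[1L]
        idx <- which(D <= r & upper.tri(D), arr.ind = TRUE)
        ring_r <- cand[cand > r][1L]
        ring <- which(abs(D - ring_r) < 1e-12 & upper.tri(D),
                      arr.ind = TRUE)
        ring <- ring[order(ring[, 1L], ring[, 2L]), , drop = FALSE]
        need <- ceiling(target_degree[1L] * n / 2) - nrow(idx)
        idx <- rbind(idx, ring[seq_len(max(0L, min(need, nrow(ring)))), ,
                               drop = FALSE])
        return(undirected_unique(cbind(idx[, 1L], idx[, 2L])))
      }
    }
    idx <- which(D <= r & upper.tri(D), arr.ind = TRUE)
    pairs <- cbind(idx[, 1L], idx[, 2L])
  }
  undirected_unique(pairs)
}

# canonical unordered edge matrix: u < v, sorted, deduplicated
undirected_unique <- function(pairs) {
  if (length(pairs) == 0L || nrow(pairs) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("u", "v"))))
  u <- pmin(pairs[, 1L], pairs[, 2L])
  v <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- u != v
  u <- u[keep]; v <- v[keep]
  key <- paste(u, v)
  d <- !duplicated(key)
  o <- order(u[d], v[d])
  out <- cbind(u = as.integer(u[d][o]), v = as.integer(v[d][o]))
  out
}

# deterministic k nearest rows of `to` for each row of `from`
# (ties broken by lowest index); exact search
knn_index <- function(from, to, k) {
  nt <- nrow(to)
  if (nt <= 2000L) {
    D <- outer(rowSums(from^2), rep(1, nt)) +
      outer(rep(1, nrow(from)), rowSums(to^2)) - 2 * tcrossprod(from, to)
    idx <- apply(D, 1L, function(d) order(d, seq_len(nt))[seq_len(k)])
    if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
  } else {
    FNN::get.knnx(to, from, k = k)$nn.index
  }
}

#' Inter-slice mutual nearest neighbour edges
#'
#' For every ordered slice pair, spot u (slice i) and spot v (slice j) are
#' linked iff each is among the other's `k_mnn` nearest neighbours in
#' feature space. Features default to the top `n_pcs` principal components
#' of the gene-standardized expression, compared under cosine distance.
#'
#' @param dataset A `multislice_dataset`, or a plain spots x features matrix
#'   together with `slice_of`.
#' @param slice_of 0-based slice index per spot (taken from `dataset` when
#'   it is a `multislice_dataset`).
#' @param k_mnn Neighbours per direction; reduced with a warning for slices
#'   with fewer spots.
#' @param n_pcs Number of principal components for the feature space.
#' @param features Optional precomputed spots x features matrix overriding
#'   the PC computation.
#' @return Two-column integer edge matrix (u < v), global spot indices.
#' @export
build_mnn_edges <- function(dataset, slice_of = NULL, k_mnn = 5L,
                            n_pcs = 50L, features = NULL) {
  if (inherits(dataset, "multislice_dataset")) {
    slice_of <- dataset$slice_of
    if (is.null(features)) features <- pca_features(dataset$X, n_pcs)
  } else if (is.null(features)) {
    features <- as.matrix(dataset)
  }
  stopifnot(!is.null(slice_of), nrow(features) == length(slice_of))
  if (length(unique(slice_of)) < 2L) stop("need >= 2 slices", call. = FALSE)
  # cosine distance == monotone in euclidean distance on l2-normalized rows
  nrm <- sqrt(rowSums(features^2))
  features <- features / pmax(nrm, 1e-12)
  sl <- sort(unique(slice_of))
  idx_of <- lapply(sl, function(s) which(slice_of == s))
  edges <- list()
  for (a in seq_along(sl)) for (b in seq_along(sl)) {
    if (a >= b) next
    ia <- idx_of[[a]]; ib <- idx_of[[b]]
    k <- min(k_mnn, length(ia), length(ib))
    if (k < k_mnn)
      warning(sprintf("k_mnn reduced to %d for slice pair (%d,%d)", k,
                      sl[a], sl[b]), call. = FALSE)
    nn_ab <- knn_index(features[ia, , drop = FALSE],
                       features[ib, , drop = FALSE], k)
    nn_ba <- knn_index(features[ib, , drop = FALSE],
                       features[ia, , drop = FALSE], k)
    # membership test: v in nn_ab[u,] and u in nn_ba[v,]
    cand <- cbind(rep(seq_along(ia), each = k), as.vector(t(nn_ab)))
    mutual <- vapply(seq_len(nrow(cand)), function(r)
      cand[r, 1L] %in% nn_ba[cand[r, 2L], ], TRUE)
    cand <- cand[mutual, , drop = FALSE]
    if (nrow(cand) > 0L)
      edges[[length(edges) + 1L]] <- cbind(ia[cand[, 1L]], ib[cand[, 2L]])
  }
  undirected_unique(do.call(rbind, c(edges, list(matrix(integer(0), 0L, 2L)))))
}

# top principal components of gene-standardized expression, spots in rows
pca_features <- function(X, n_pcs = 50L) {
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  keep <- sdv > 0
  Xs <- t((X[keep, , drop = FALSE] - mu[keep]) / sdv[keep])
  n_pcs <- min(n_pcs, ncol(Xs) - 1L, nrow(Xs) - 1L)
  if (min(dim(Xs)) <= 300L) {
    p <- prcomp(Xs, center = TRUE, scale. = FALSE, rank. = n_pcs)
    p$x
  } else {
    # truncated PCA with a fixed internal seed and sign convention
    # (largest-|loading| positive) so the feature space is deterministic
    p <- with_seed(760123L,
      irlba::prcomp_irlba(Xs, n = n_pcs, center = TRUE, scale. = FALSE))
    sgn <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
    sweep(p$x, 2L, sgn, "*")
  }
}

#' Assemble the unified multi-slice graph
#'
#' Union of intra-slice spatial edges and inter-slice MNN edges over all
#' spots, with provenance retained, at iteration counter `it = 0`.
#'
#' @param intra_sets List of per-slice edge matrices in *local* spot indices
#'   (as returned by [build_intra_edges()]), ordered by slice; or a single
#'   edge matrix already in global indices (then set `global = TRUE`).
#' @param inter_set Edge matrix in global indices from [build_mnn_edges()].
#' @param slice_of 0-based slice index per spot.
#' @param global If `TRUE`, `intra_sets` is a single global-index matrix.
#' @return A `unified_graph`: `n`, `edges` (u, v, provenance), `it`.
#' @export
unified_graph <- function(intra_sets, inter_set, slice_of, global = FALSE) {
  n <- length(slice_of)
  if (global) {
    intra <- undirected_unique(as.matrix(intra_sets))
  } else {
    offs <- cumsum(c(0L, tabulate(slice_of + 1L)))
    intra <- do.call(rbind, lapply(seq_along(intra_sets), function(i) {
      e <- intra_sets[[i]]
      if (nrow(e) == 0L) return(e)
      e + offs[i]
    }))
    intra <- undirected_unique(intra)
  }
  inter <- undirected_unique(as.matrix(inter_set))
  if (nrow(intra) > 0L &&
      any(slice_of[intra[, 1L]] != slice_of[intra[, 2L]]))
    stop("intra edges must connect same-slice spots", call. = FALSE)
  if (nrow(inter) > 0L &&
      any(slice_of[inter[, 1L]] == slice_of[inter[, 2L]]))
    stop("inter edges must connect different-slice spots", call. = FALSE)
  ed <- rbind(intra, inter)
  if (nrow(ed) > 0L && (min(ed) < 1L || max(ed) > n))
    stop("edge endpoints out of range", call. = FALSE)
  prov <- rep(c("intra", "inter"), c(nrow(intra), nrow(inter)))
  key <- paste(ed[, 1L], ed[, 2L])
  d <- !duplicated(key)       # an edge present in both sets keeps 'intra'
  edges <- data.frame(u = ed[d, 1L], v = ed[d, 2L], provenance = prov[d],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges, it = 0L, slice_of = slice_of),
            class = "unified_graph")
}

#' @export
print.unified_graph <- function(x, ...) {
  cat(sprintf("<unified_graph> %d spots, %d edges (%d intra, %d inter), it=%d\n",
              x$n, nrow(x$edges), sum(x$edges$provenance == "intra"),
              sum(x$edges$provenance == "inter"), x$it))
  invisible(x)
}

#' Sparse symmetric adjacency of a unified graph
#'
#' @param graph A `unified_graph`.
#' @param self_loops Add the identity (model-time convention).
#' @return A sparse 0/1 `dgCMatrix`.
#' @export
graph_adjacency <- function(graph, self_loops = FALSE) {
  e <- graph$edges
  A <- Matrix::sparseMatrix(i = c(e$u, e$v), j = c(e$v, e$u),
                            x = 1, dims = c(graph$n, graph$n))
  A@x[] <- 1  # collapse duplicates to binary
  if (self_loops) A <- A + Matrix::Diagonal(graph$n)
  A@x[] <- pmin(A@x, 1)
  A
}

#' Remove edges crossing mixture components
#'
#' Keeps only edges whose endpoints share the same assignment; increments
#' the graph's iteration counter. Pruning is removal-only.
#'
#' @param graph A `unified_graph`.
#' @param assignments Integer component label per spot (length `n`).
#' @return The pruned `unified_graph` with `it + 1`.
#' @export
prune_graph <- function(graph, assignments) {
  stopifnot(inherits(graph, "unified_graph"))
  if (length(assignments) != graph$n)
    stop("assignment length mismatch", call. = FALSE)
  keep <- assignments[graph$edges$u] == assignments[graph$edges$v]
  graph$edges <- graph$edges[keep, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph$it <- graph$it + 1L
  graph
}

#' Write / read a unified graph as a 3-column edge-list TSV
#' @param graph A `unified_graph`.
#' @param path Output TSV (columns u, v, provenance).
#' @export
write_graph_tsv <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param slice_of 0-based slice membership (restored on read).
#' @export
read_graph_tsv <- function(path, slice_of) {
  e <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  intra <- as.matrix(e[e$provenance == "intra", c("u", "v")])
  inter <- as.matrix(e[e$provenance == "inter", c("u", "v")])
  unified_graph(intra, inter, slice_of, global = TRUE)
}
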
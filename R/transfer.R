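# Zero-shot label transfer: a new slice is mapped through the frozen
# trained encoder on its own intra-slice spatial graph and labelled from
# nearest reference spots in latent space. Reference latents stored in the
# bundle are recomputed per slice under the same intra-only graph rule, so
# reference and query pass through the identical frozen map.

#' Build a reference bundle for zero-shot transfer
#'
#' Freezes the trained encoder together with the reference gene list, the
#' normalization target, the intra-edge rule, per-spot labels, and
#' reference latents computed per slice with the intra-slice-only graph
#' (the same rule a query gets).
#'
#' @param fit A `fit_result` from [integrate_slices()]/[fit_dynamic()].
#' @param dataset The `multislice_dataset` the model was trained on.
#' @param labels Per-spot labels to transfer (e.g. cluster assignments or
#'   domain annotations); defaults to `fit$assignments`.
#' @param intra_k k used for intra-slice knn graphs.
#' @return A `reference_bundle`.
#' @export
build_reference <- function(fit, dataset, labels = NULL, intra_k = 6L) {
  labels <- labels %||% fit$assignments
  stopifnot(length(labels) == ncol(dataset$X))
  n <- ncol(dataset$X)
  z_ref <- matrix(0, n, ncol(fit$z))
  for (i in seq_len(dataset$L) - 1L) {
    sel <- dataset$slice_of == i
    z_ref[sel, ] <- encode_intra_only(dataset$X[, sel, drop = FALSE],
                                      dataset$S[sel, , drop = FALSE],
                                      fit$model$enc, intra_k)
  }
  structure(list(enc = fit$model$enc, gene_ids = dataset$gene_ids,
                 target_sums = dataset$target_sums,
                 intra_k = intra_k, z_ref = z_ref, labels = labels),
            class = "reference_bundle")
}

encode_intra_only <- function(Xi, coords, enc, intra_k) {
  e <- build_intra_edges(coords, mode = "knn", k = intra_k)
  g <- unified_graph(list(e), matrix(integer(0), 0L, 2L),
                     slice_of = rep(0L, ncol(Xi)))
  encode(Xi, g, enc, eval_mode = TRUE)$mu
}

#' Embed a query slice with the frozen reference encoder
#'
#' The query is normalized like the reference, restricted and reordered to
#' the reference gene list (missing genes zero-filled with a warning; less
#' than 50% overlap is an error), given an intra-slice spatial graph, and
#' encoded in evaluation mode without any parameter update.
#'
#' @param bundle A [build_reference()] bundle.
#' @param query A [raw_slice()] (raw counts, or already normalized with
#'   `normalized = TRUE`).
#' @return n_q x d latent matrix.
#' @export
embed_query <- function(bundle, query) {
  stopifnot(inherits(bundle, "reference_bundle"),
            inherits(query, "raw_slice"))
  if (!isTRUE(query$normalized)) {
    ts <- bundle$target_sums
    ts <- if (all(is.na(ts))) NULL else median(ts, na.rm = TRUE)
    query <- normalize_log(query, target_sum = ts)
  }
  hit <- match(bundle$gene_ids, query$gene_ids)
  overlap <- mean(!is.na(hit))
  if (overlap < 0.5)
    stop(sprintf("only %.0f%% of reference genes found in query",
                 100 * overlap), call. = FALSE)
  if (overlap < 1)
    warning(sprintf("%d reference genes missing in query; zero-filled",
                    sum(is.na(hit))), call. = FALSE)
  Xq <- matrix(0, length(bundle$gene_ids), ncol(query$counts))
  Xq[!is.na(hit), ] <- query$counts[hit[!is.na(hit)], , drop = FALSE]
  encode_intra_only(Xq, query$coords, bundle$enc, bundle$intra_k)
}

#' Transfer labels by latent-space nearest neighbours
#'
#' Majority vote among the `k` Euclidean nearest reference spots; vote ties
#' are broken by the single nearest neighbour's label.
#'
#' @param z_ref Reference latent matrix (n_ref x d).
#' @param labels_ref Reference labels (length n_ref).
#' @param z_q Query latent matrix.
#' @param k Neighbours (<= n_ref).
#' @return data.frame with `label` and `confidence` (vote fraction).
#' @export
transfer_labels <- function(z_ref, labels_ref, z_q, k = 5L) {
  z_ref <- as.matrix(z_ref); z_q <- as.matrix(z_q)
  stopifnot(k <= nrow(z_ref), length(labels_ref) == nrow(z_ref))
  nn <- knn_index(z_q, z_ref, k)
  lab <- character(nrow(z_q)); conf <- numeric(nrow(z_q))
  labs <- as.character(labels_ref)
  for (i in seq_len(nrow(z_q))) {
    votes <- table(labs[nn[i, ]])
    top <- votes[votes == max(votes)]
    lab[i] <- if (length(top) > 1L) labs[nn[i, 1L]] else names(top)
    conf[i] <- max(votes) / k
  }
  data.frame(label = lab, confidence = conf, stringsAsFactors = FALSE)
}
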
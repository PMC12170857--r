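#' Construct a single-slice container
#'
#' Holds one tissue section: a genes-by-spots matrix, spot coordinates, and
#' optional slice-level clinical information.
#'
#' @param counts Non-negative genes x spots matrix (raw counts or, for
#'   precomputed multi-omics features, any real matrix — see
#'   [assemble_dataset()]).
#' @param gene_ids Unique gene identifiers, one per row.
#' @param coords Spots x 2 coordinate matrix.
#' @param slice_id Slice identifier.
#' @param clinical Optional list with either `time` (> 0) and `event`
#'   (0/1), or `class`.
#' @return A `raw_slice` object.
#' @export
raw_slice <- function(counts, gene_ids = rownames(counts), coords,
                      slice_id, clinical = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  if (is.null(gene_ids)) stop("gene_ids required", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique within a slice", call. = FALSE)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length must match row count", call. = FALSE)
  if (nrow(coords) != ncol(counts))
    stop("coords row count must equal spot count", call. = FALSE)
  if (ncol(coords) != 2L) stop("coords must have 2 columns", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(clinical) && !is.null(clinical$time) && any(clinical$time <= 0))
    stop("survival_time must be > 0", call. = FALSE)
  rownames(counts) <- gene_ids
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 coords = coords, slice_id = as.character(slice_id),
                 clinical = clinical, normalized = FALSE),
            class = "raw_slice")
}

#' @export
print.raw_slice <- function(x, ...) {
  cat(sprintf("<raw_slice '%s'> %d genes x %d spots%s\n", x$slice_id,
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Per-spot total-count normalization followed by log1p
#'
#' Scales every spot (column) to a common target sum, then applies
#' `log1p`. All-zero spots stay all-zero.
#'
#' @param raw A [raw_slice()].
#' @param target_sum Common per-spot total after scaling; default the median
#'   per-spot total of the slice (zero-total spots excluded from the median).
#' @return The slice with normalized, log-transformed `counts`
#'   (`normalized = TRUE`); `target_sum` used is recorded.
#' @export
normalize_log <- function(raw, target_sum = NULL) {
  stopifnot(inherits(raw, "raw_slice"))
  tot <- colSums(raw$counts)
  if (all(tot == 0)) stop("empty slice", call. = FALSE)
  target_sum <- target_sum %||% median(tot[tot > 0])
  sf <- ifelse(tot > 0, target_sum / tot, 0)
  raw$counts <- log1p(sweep(raw$counts, 2L, sf, "*"))
  raw$normalized <- TRUE
  raw$target_sum <- target_sum
  raw
}

# Seurat-flavour mean-binned normalized dispersion: statistics on the
# linear (expm1) scale of the log-normalized data, z-scored within
# equal-frequency mean bins.
hvg_rank <- function(mat, n_bins = 20L) {
  lin <- expm1(mat)
  mu <- rowMeans(lin)
  v <- apply(lin, 1L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = n_bins, labels = FALSE)  # equal-width mean bins
  zd <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- stats::sd(disp[sel])
    zd[sel] <- if (is.na(s) || s == 0) 0 else (disp[sel] - mean(disp[sel])) / s
  }
  zd
}

#' Select highly variable genes per slice and intersect across slices
#'
#' Ranks genes within each slice by mean-binned normalized dispersion on the
#' normalized log data, takes the top `n_hvg` per slice, and returns the
#' intersection, sorted.
#'
#' @param slices List of normalized [raw_slice()] objects (>= 2).
#' @param n_hvg Genes per slice before intersecting; a slice with fewer
#'   genes contributes all of them.
#' @param warn_below Warn and suggest a larger `n_hvg` when the intersection
#'   is smaller than this.
#' @return Character vector of common genes (sorted).
#' @export
select_common_hvgs <- function(slices, n_hvg = 5000L, warn_below = 1000L) {
  stopifnot(length(slices) >= 2L)
  sets <- lapply(slices, function(s) {
    stopifnot(inherits(s, "raw_slice"))
    if (nrow(s$counts) <= n_hvg) return(s$gene_ids)
    zd <- hvg_rank(s$counts)
    ord <- order(-zd, s$gene_ids)
    s$gene_ids[ord[seq_len(n_hvg)]]
  })
  common <- Reduce(intersect, sets)
  if (length(common) == 0L)
    stop(sprintf("empty HVG intersection (per-slice HVG counts: %s)",
                 paste(lengths(sets), collapse = ", ")), call. = FALSE)
  if (length(common) < warn_below)
    warning(sprintf(paste0("HVG intersection has only %d genes; consider a ",
                           "larger n_hvg"), length(common)), call. = FALSE)
  sort(common)
}

#' Assemble slices into a multi-slice dataset
#'
#' Restricts every slice to the common genes (same order everywhere) and
#' concatenates spots slice-by-slice.
#'
#' @param slices List of [raw_slice()] objects (normalized, or precomputed
#'   feature matrices in multi-omics mode).
#' @param common_genes Genes to keep, e.g. from [select_common_hvgs()].
#' @return A `multislice_dataset`: `X` (genes x spots), `slice_of` (0-based
#'   slice index per spot), `S` (spots x 2 coordinates), `L`, `gene_ids`,
#'   `slice_ids`, `Y` (clinical records or NULL), `target_sums`.
#' @export
assemble_dataset <- function(slices, common_genes) {
  stopifnot(length(slices) >= 1L)
  for (s in slices) {
    miss <- setdiff(common_genes, s$gene_ids)
    if (length(miss) > 0L)
      stop(sprintf("slice '%s' is missing gene '%s'", s$slice_id, miss[1L]),
           call. = FALSE)
  }
  X <- do.call(cbind, lapply(slices, function(s)
    s$counts[match(common_genes, s$gene_ids), , drop = FALSE]))
  rownames(X) <- common_genes
  n_i <- vapply(slices, function(s) ncol(s$counts), 0L)
  S <- do.call(rbind, lapply(slices, function(s) unname(s$coords)))
  Y <- lapply(slices, function(s) s$clinical)
  if (all(vapply(Y, is.null, TRUE))) Y <- NULL
  structure(list(X = X, slice_of = rep(seq_along(slices) - 1L, n_i),
                 S = S, L = length(slices),
                 gene_ids = as.character(common_genes),
                 slice_ids = vapply(slices, function(s) s$slice_id, ""),
                 Y = Y,
                 target_sums = vapply(slices, function(s)
                   s$target_sum %||% NA_real_, 0)),
            class = "multislice_dataset")
}

#' @export
print.multislice_dataset <- function(x, ...) {
  cat(sprintf("<multislice_dataset> %d genes x %d spots, %d slices\n",
              nrow(x$X), ncol(x$X), x$L))
  invisible(x)
}

#' Estimate the number of mixture components from the data spectrum
#'
#' Counts the eigenvalues of the gene-standardized Gram matrix that exceed
#' the Marchenko-Pastur upper bulk edge, i.e. the directions carrying more
#' variance than a pure-noise matrix of the same shape would; the count is
#' clamped to `[k_min, k_max]`.
#'
#' @param X Genes x spots matrix (finite).
#' @param k_min,k_max Clamp range for the returned K.
#' @return Integer K.
#' @export
estimate_k <- function(X, k_min = 2L, k_max = 30L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  keep <- sdv > 0
  if (!any(keep)) stop("degenerate X: zero variance after standardization",
                       call. = FALSE)
  Xs <- (X[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  m_eff <- nrow(Xs)
  # eigenvalues of (1/m) Xs^T Xs via singular values
  nv <- min(m_eff, n, max(k_max + 5L, 40L))
  sv <- if (min(m_eff, n) <= 500L) {
    svd(Xs, nu = 0L, nv = 0L)$d
  } else {
    irlba::irlba(Xs, nv = nv, nu = 0L, work = nv + 10L)$d
  }
  ev <- sv^2 / m_eff
  edge <- (1 + sqrt(n / m_eff))^2
  k <- sum(ev > edge)
  as.integer(min(max(k, k_min), k_max))
}
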
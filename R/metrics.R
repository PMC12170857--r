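# Evaluation metrics: clustering agreement (ARI, NMI), embedding quality
# (silhouette/ASW, F1 mixing score, LISI), and clinical prediction
# (C-index, accuracy, AUROC). All implemented from their definitions.

#' Adjusted Rand index between two partitions
#' @param a,b Label vectors of equal length.
#' @return Scalar in `[-1, 1]`; 1 for identical partitions.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(0)
  (sum_ij - expected) / (mx - expected)
}

#' Normalized mutual information (arithmetic-mean normalization)
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    p <- tab[i, j]
    if (p > 0) mi <- mi + p * log(p / (pa[i] * pb[j]))
  }
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  as.numeric(mi / ((ha + hb) / 2))
}

#' Average silhouette width
#'
#' Per spot: `(b - a) / max(a, b)` where `a` is the mean within-cluster
#' Euclidean distance (excluding self) and `b` the smallest mean distance
#' to another cluster. Singleton-cluster spots score 0.
#'
#' @param features n x d matrix.
#' @param labels Cluster labels (>= 2 distinct).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_asw <- function(features, labels) {
  labels <- as.character(labels)
  ul <- unique(labels)
  if (length(ul) < 2L) stop("need >= 2 distinct labels", call. = FALSE)
  D <- as.matrix(dist(as.matrix(features)))
  n <- length(labels)
  sw <- numeric(n)
  idx <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- idx[[labels[i]]]
    if (length(own) == 1L) { sw[i] <- 0; next }
    a_i <- sum(D[i, own]) / (length(own) - 1L)
    b_i <- min(vapply(idx[names(idx) != labels[i]],
                      function(o) mean(D[i, o]), 0))
    m <- max(a_i, b_i)
    sw[i] <- if (m == 0) 0 else (b_i - a_i) / m
  }
  mean(sw)
}

#' F1 slice-mixing score
#'
#' Combines cluster-label ASW (purity) and slice-label ASW (mixing) after
#' shifting both to `[0, 1]`: `F1 = 2 (1-ASW'_slice) ASW'_cluster /
#' (ASW'_cluster + (1-ASW'_slice))`. Higher is better integration.
#'
#' @param asw_slice,asw_cluster ASW values in `[-1, 1]`.
#' @return Scalar in `[0, 1]`; 0 when the denominator vanishes.
#' @export
f1_mix <- function(asw_slice, asw_cluster) {
  stopifnot(abs(asw_slice) <= 1, abs(asw_cluster) <= 1)
  s <- (1 + asw_slice) / 2
  c_ <- (1 + asw_cluster) / 2
  den <- c_ + (1 - s)
  if (den == 0) return(0)
  2 * (1 - s) * c_ / den
}

#' Local inverse Simpson's index of label diversity
#'
#' Per spot, neighbour weights are a Gaussian kernel over the
#' `3*perplexity` nearest spots with bandwidth tuned by bisection so the
#' weight entropy equals `log(perplexity)`; the score is the inverse
#' Simpson index of the label distribution under those weights. Applied to
#' slice labels this is iLISI (batch mixing), to cluster labels cLISI
#' (purity).
#'
#' @param embedding n x d matrix.
#' @param labels Label vector.
#' @param perplexity Effective neighbourhood size; requires
#'   `n > perplexity`.
#' @return List with `scores` (per spot, in `[1, #labels]`) and `mean`.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n <= perplexity) stop("n must exceed perplexity", call. = FALSE)
  labels <- as.integer(factor(labels))
  nl <- max(labels)
  k <- min(3L * ceiling(perplexity), n - 1L)
  nn <- knn_index(embedding, embedding, k + 1L)
  target <- log(perplexity)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- setdiff(nn[i, ], i)[seq_len(k)]
    d2 <- rowSums((embedding[nbr, , drop = FALSE] -
                     matrix(embedding[i, ], k, ncol(embedding),
                            byrow = TRUE))^2)
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in seq_len(100L)) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-10) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * d2); p <- w / sum(w)
    pl <- vapply(seq_len(nl), function(l) sum(p[labels[nbr] == l]), 0)
    scores[i] <- 1 / sum(pl^2)
  }
  list(scores = scores, mean = mean(scores))
}

#' Concordance index for survival predictions
#'
#' Fraction of comparable pairs (the earlier time had an event) in which
#' the higher predicted risk had the shorter time; score ties count 0.5.
#'
#' @param scores Predicted risk scores (higher = higher hazard).
#' @param times Survival or censoring times.
#' @param events Event indicators (1 = observed).
#' @return Scalar in `[0, 1]`; 0.5 is random.
#' @export
c_index <- function(scores, times, events) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- times[j] > times[i] ||
        (times[j] == times[i] && events[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  num / den
}

#' Accuracy and AUROC of class predictions
#'
#' AUROC is the Mann-Whitney rank statistic (ties at 0.5); for more than
#' two classes the macro average of one-vs-rest AUROCs is returned.
#'
#' @param scores For binary labels, a vector of scores for the positive
#'   (second) class; for multiclass, an n x P matrix of class scores.
#' @param labels True class labels.
#' @param predicted Optional hard predictions for the accuracy; defaults to
#'   thresholding `scores` at 0.5 (binary) or the argmax (multiclass).
#' @return List with `acc` and `auc`.
#' @export
acc_auc <- function(scores, labels, predicted = NULL) {
  labels <- factor(labels)
  lv <- levels(labels)
  if (length(lv) < 2L) stop("single-class data", call. = FALSE)
  auc1 <- function(s, pos) {
    x <- s[pos]; y <- s[!pos]
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    r <- rank(c(x, y))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(y))
  }
  if (is.matrix(scores) && ncol(scores) > 1L) {
    aucs <- vapply(seq_along(lv), function(p)
      auc1(scores[, p], labels == lv[p]), 0)
    auc <- mean(aucs, na.rm = TRUE)
    pred <- predicted %||% lv[max.col(scores, ties.method = "first")]
  } else {
    s <- drop(as.matrix(scores))
    auc <- auc1(s, labels == lv[2L])
    pred <- predicted %||% lv[1L + as.integer(s > 0.5)]
  }
  list(acc = mean(as.character(pred) == as.character(labels)), auc = auc)
}
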
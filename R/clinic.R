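# Supervised stage: each slice is summarized by ten statistics (mean,
# variance, max, min of the two shared UMAP axes per cluster, plus the
# cluster's within-slice and other-slice proportions); an attention
# mechanism pools the ten K-vectors into one cluster-space representation
# per slice, and a Cox or softmax head links it to clinical outcomes. The
# transposed head weights are the per-cluster clinical importances.

MEASURES <- c("mean_u1", "mean_u2", "var_u1", "var_u2", "max_u1", "max_u2",
              "min_u1", "min_u2", "P_within", "P_other")

#' Shared 2-D UMAP embedding of the latent space
#'
#' One embedding fitted jointly on all spots so slices and clusters live in
#' a comparable space. Deterministic under `seed`.
#'
#' @param z n x d latent matrix (n >= 10).
#' @param seed Seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return n x 2 matrix.
#' @export
embed_umap <- function(z, seed = 1L, n_neighbors = 30L, min_dist = 0.3) {
  z <- as.matrix(z)
  if (nrow(z) < 10L) stop("need at least 10 spots", call. = FALSE)
  nb <- min(n_neighbors, nrow(z) - 1L)
  with_seed(seed,
    uwot::umap(z, n_neighbors = nb, min_dist = min_dist, n_threads = 1L,
               n_sgd_threads = 0L))
}

#' Per-slice, per-cluster geometric statistics of a shared embedding
#'
#' For every slice i and cluster k: mean, population variance, max, min of
#' each embedding axis over the slice's cluster-k spots; `P_within` =
#' cluster share within the slice; `P_other` = share of cluster-k spots
#' among all spots of the other slices. A cluster absent from a slice
#' yields ten zeros.
#'
#' @param embedding n x 2 matrix (e.g. [embed_umap()]).
#' @param assignments 1-based cluster label per spot.
#' @param slice_of 0-based slice index per spot.
#' @param K Number of clusters.
#' @return L x 10 x K array (`slice_feature`), measures as in the second
#'   dimension's dimnames.
#' @export
slice_statistics <- function(embedding, assignments, slice_of, K) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2L, all(assignments >= 1L),
            all(assignments <= K))
  sl <- sort(unique(slice_of))
  L <- length(sl)
  F_ <- array(0, dim = c(L, 10L, K),
              dimnames = list(NULL, MEASURES, NULL))
  n <- length(slice_of)
  for (ii in seq_len(L)) {
    in_i <- slice_of == sl[ii]
    n_i <- sum(in_i)
    for (k in seq_len(K)) {
      sel <- in_i & assignments == k
      cnt <- sum(sel)
      other <- sum(!in_i & assignments == k)
      if (cnt > 0L) {
        e <- embedding[sel, , drop = FALSE]
        mu <- colMeans(e)
        v <- colMeans(e^2) - mu^2          # population variance
        F_[ii, , k] <- c(mu, v, apply(e, 2L, max), apply(e, 2L, min),
                         cnt / n_i,
                         if (n > n_i) other / (n - n_i) else 0)
      } else {
        F_[ii, "P_other", k] <- 0  # fill rule: all ten entries stay 0
      }
    }
  }
  structure(F_, class = c("slice_feature", "array"))
}

# z-score each of the 10K features across slices; constants -> 0
standardize_features <- function(F_, center = NULL, scale = NULL) {
  dm <- dim(F_)
  M <- matrix(F_, nrow = dm[1L])   # L x (10*K), column = (measure, cluster)
  center <- center %||% colMeans(M)
  scale_ <- scale %||% apply(M, 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Ms <- sweep(sweep(M, 2L, center), 2L, scale_, "/")
  out <- array(Ms, dim = dm, dimnames = dimnames(F_))
  attr(out, "center") <- center
  attr(out, "scale") <- scale_
  out
}

#' Attention pooling of slice statistics into a cluster-space representation
#'
#' Attention logit j is the inner product of `a_j` with the concatenation
#' of all ten measure K-vectors of the slice; the weights are a softmax
#' over the ten measures and the pooled representation is the
#' weight-averaged K-vector.
#'
#' @param F_i 10 x K matrix of one slice's (standardized) statistics.
#' @param a 10 x (10K) matrix whose rows are the attention vectors `a_j`.
#' @param bias Optional per-measure logit offset (length 10; default zero,
#'   the bias-free scoring). A trained bias lets the head prefer a measure
#'   uniformly across slices.
#' @return List with `r` (length-K representation) and `lambda` (length-10
#'   weights summing to 1).
#' @export
attention_pool <- function(F_i, a, bias = NULL) {
  F_i <- as.matrix(F_i)
  stopifnot(nrow(F_i) == 10L, ncol(a) == length(F_i))
  v <- as.vector(t(F_i))                 # concat of the ten K-vectors
  lambda <- softmax(drop(a %*% v) + (bias %||% 0))
  list(r = drop(crossprod(F_i, lambda)), lambda = lambda)
}

#' Negative Cox partial log-likelihood
#'
#' Sum over non-censored slices of `-(y_i - log sum_{t_j >= t_i} exp y_j)`;
#' tied event times share the same risk set (Breslow); censored slices
#' contribute to risk sets only.
#'
#' @param scores Predicted log-hazard scores.
#' @param times Survival/censoring times (> 0).
#' @param events Event indicators in {0, 1}.
#' @return Non-negative scalar.
#' @export
cox_loss <- function(scores, times, events) {
  stopifnot(length(scores) == length(times), all(times > 0),
            all(events %in% c(0, 1)))
  if (sum(events) == 0) stop("no non-censored slices", call. = FALSE)
  loss <- 0
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    loss <- loss - (scores[i] - logsumexp(scores[risk]))
  }
  loss
}

# gradient of cox_loss wrt scores
cox_loss_grad <- function(scores, times, events) {
  g <- numeric(length(scores))
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    w <- exp(scores[risk] - logsumexp(scores[risk]))
    g[i] <- g[i] - 1
    g[risk] <- g[risk] + w
  }
  g
}

#' Mean categorical cross-entropy over slices
#'
#' @param probabilities L x P matrix of predicted class probabilities
#'   (rows sum to 1).
#' @param labels Integer class index (1-based) or factor, length L.
#' @param clip Probability clipping constant.
#' @return Non-negative scalar.
#' @export
classify_loss <- function(probabilities, labels, clip = 1e-12) {
  probabilities <- as.matrix(probabilities)
  lab <- as.integer(factor(labels))
  stopifnot(nrow(probabilities) == length(lab))
  p <- probabilities[cbind(seq_along(lab), lab)]
  mean(-log(pmax(p, clip)))
}

#' Fit the attention-pooled clinical head
#'
#' Jointly optimizes the ten attention vectors and the linear head by Adam
#' on the Cox partial likelihood (survival) or softmax cross-entropy
#' (classification), with L2 regularization. The transposed head weights
#' are returned as per-cluster clinical importances.
#'
#' @param F_ L x 10 x K [slice_statistics()] array.
#' @param Y For `task = "cox"`: data.frame with `time`, `event`; for
#'   `"classify"`: a vector/factor of per-slice classes.
#' @param task `"cox"` or `"classify"`.
#' @param lr,epochs,l2 Optimization settings. `l2` is calibrated to the
#'   scale of the summed Cox partial likelihood; for the classification
#'   task (a per-slice mean loss) it is rescaled by `1/L` internally so
#'   the effective regularization strength is comparable across tasks.
#' @param seed Seed for parameter initialization.
#' @param standardize Standardize features across slices (recommended; the
#'   fitted centering/scaling is stored for prediction).
#' @return A `clinic_head`: `a` (10 x 10K), `W`, `b`, `task`,
#'   `cluster_weights` (K, or P x K for classification), per-slice `scores`
#'   and attention `lambda`, the feature standardization, and the final
#'   loss.
#' @export
fit_clinic_head <- function(F_, Y, task = c("cox", "classify"), lr = 1e-2,
                            epochs = 1000L, l2 = 0.2, seed = 1L,
                            standardize = TRUE) {
  task <- match.arg(task)
  dm <- dim(F_)
  L <- dm[1L]; K <- dm[3L]
  if (task == "cox") {
    stopifnot(is.data.frame(Y), L >= 4L)
    times <- Y$time; events <- Y$event
    if (sum(events) == 0) stop("no non-censored slices", call. = FALSE)
    P <- 1L
  } else {
    lab <- as.integer(factor(Y))
    P <- max(lab)
    if (P < 2L) stop("single-class data", call. = FALSE)
    if (any(tabulate(lab, P) < 2L))
      stop("need >= 2 slices per class", call. = FALSE)
  }
  # the cox loss is a sum over events, the classification loss a mean over
  # slices; rescale the penalty so both tasks see a comparable strength
  l2_eff <- if (task == "classify") l2 / L else l2
  Fs <- if (standardize) standardize_features(F_) else F_
  Fmats <- lapply(seq_len(L), function(i)
    matrix(Fs[i, , ], 10L, K))          # 10 x K per slice
  Vs <- vapply(Fmats, function(Fm) as.vector(t(Fm)), numeric(10L * K))
  # zero-symmetric start: attention begins uniform over the ten measures
  # and sharpens only where the head finds signal; small seeded jitter on W
  # breaks exact class symmetry for the softmax task
  ps <- with_seed(seed, list(
    a = matrix(0, 10L, 10L * K), ba = numeric(10L),
    W = matrix(rnorm(P * K, 0, 1e-3), P, K),
    b = numeric(P)))
  st <- adam_init(ps)
  forward <- function(ps) {
    lam <- matrix(0, L, 10L)
    R <- matrix(0, L, K)
    for (i in seq_len(L)) {
      lg <- drop(ps$a %*% Vs[, i]) + ps$ba
      lam[i, ] <- softmax(lg)
      R[i, ] <- drop(crossprod(Fmats[[i]], lam[i, ]))
    }
    scores <- R %*% t(ps$W) + rep(ps$b, each = L)
    list(lam = lam, R = R, scores = scores)
  }
  loss_and_dscore <- function(scores) {
    if (task == "cox") {
      s <- drop(scores)
      list(loss = cox_loss(s, times, events),
           d = matrix(cox_loss_grad(s, times, events), ncol = 1L))
    } else {
      pr <- row_softmax(scores)
      hot <- matrix(0, L, P); hot[cbind(seq_len(L), lab)] <- 1
      list(loss = classify_loss(pr, lab), d = (pr - hot) / L)
    }
  }
  final_loss <- NA_real_
  prev <- Inf
  for (ep in seq_len(epochs)) {
    fw <- forward(ps)
    ld <- loss_and_dscore(fw$scores)
    if (!is.finite(ld$loss)) stop("head optimization diverged (NaN loss)",
                                  call. = FALSE)
    dS <- ld$d
    gW <- crossprod(dS, fw$R) + l2_eff * ps$W
    gb <- colSums(dS)
    ga <- ps$a * 0; gba <- numeric(10L)
    for (i in seq_len(L)) {
      dr <- drop(crossprod(ps$W, dS[i, ]))          # K
      dlam <- drop(Fmats[[i]] %*% dr)               # 10
      lam <- fw$lam[i, ]
      dlg <- lam * (dlam - sum(lam * dlam))
      ga <- ga + tcrossprod(dlg, Vs[, i])
      gba <- gba + dlg
    }
    ga <- ga + l2_eff * ps$a
    upd <- adam_step(ps, list(a = ga, ba = gba, W = gW, b = gb), st, lr)
    ps <- upd$ps; st <- upd$st
    final_loss <- ld$loss
    if (ep %% 50L == 0L) {
      if (abs(prev - ld$loss) < 1e-7 * max(1, abs(prev))) break
      prev <- ld$loss
    }
  }
  fw <- forward(ps)
  structure(list(a = ps$a, ba = ps$ba, W = ps$W, b = ps$b, task = task,
                 K = K, P = P,
                 cluster_weights = if (task == "cox") drop(ps$W) else ps$W,
                 scores = fw$scores, lambda = fw$lam,
                 center = attr(Fs, "center"), scale = attr(Fs, "scale"),
                 loss = final_loss),
            class = "clinic_head")
}

#' Predict head scores for new slice features
#'
#' @param head A `clinic_head`.
#' @param F_ L x 10 x K statistics array (unstandardized; the head's stored
#'   standardization is applied).
#' @return L x P score matrix (log-hazards for cox; class logits for
#'   classify).
#' @export
predict_head <- function(head, F_) {
  Fs <- if (!is.null(head$center))
    standardize_features(F_, head$center, head$scale) else F_
  L <- dim(F_)[1L]
  out <- matrix(0, L, head$P)
  for (i in seq_len(L)) {
    Fm <- matrix(Fs[i, , ], 10L, head$K)
    ap <- attention_pool(Fm, head$a, head$ba)
    out[i, ] <- drop(head$W %*% ap$r) + head$b
  }
  out
}

#' Cross-validated Cox prediction
#'
#' Random slice-level folds; per fold the head is trained on the training
#' slices and scores are predicted for the held-out slices. Returns the
#' median held-out C-index, per-fold values, and pooled per-slice predicted
#' hazard ratios for risk-group splitting at the median.
#'
#' @inheritParams fit_clinic_head
#' @param folds Number of folds; every fold must hold out >= 2 slices.
#' @param seed Seed (fold assignment, head initialization).
#' @param ... Passed to [fit_clinic_head()].
#' @return List with `median_cindex`, `fold_cindex`, `hr` (per-slice
#'   held-out hazard ratios), `folds`.
#' @export
cv_cox <- function(F_, Y, folds = 7L, seed = 1L, ...) {
  L <- dim(F_)[1L]
  if (folds > L) stop("more folds than slices", call. = FALSE)
  if (L / folds < 2) stop("each fold must hold out >= 2 slices", call. = FALSE)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), L)))
  cidx <- rep(NA_real_, folds)
  hr <- rep(NA_real_, L)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f); train <- which(fold_of != f)
    head <- fit_clinic_head(F_[train, , , drop = FALSE],
                            Y[train, , drop = FALSE], task = "cox",
                            seed = seed + f, ...)
    sc <- drop(predict_head(head, F_[test, , , drop = FALSE]))
    hr[test] <- exp(sc)
    if (sum(Y$event[test]) == 0) {
      warning(sprintf("fold %d has no events; skipped", f), call. = FALSE)
      next
    }
    cidx[f] <- tryCatch(c_index(sc, Y$time[test], Y$event[test]),
                        error = function(e) NA_real_)
  }
  list(median_cindex = median(cidx, na.rm = TRUE), fold_cindex = cidx,
       hr = hr, folds = fold_of)
}

#' Leave-one-out cross-validated classification
#'
#' Each slice is held out once; accuracy and AUROC (macro-averaged for
#' multiclass) are computed from the held-out predictions.
#'
#' @inheritParams fit_clinic_head
#' @param seed Seed.
#' @param ... Passed to [fit_clinic_head()].
#' @return List with `acc`, `auc`, `scores` (held-out class probabilities),
#'   `predicted`.
#' @export
cv_classify <- function(F_, Y, seed = 1L, ...) {
  L <- dim(F_)[1L]
  lab <- factor(Y)
  if (nlevels(lab) < 2L) stop("single-class data", call. = FALSE)
  P <- nlevels(lab)
  probs <- matrix(NA_real_, L, P)
  for (i in seq_len(L)) {
    train <- setdiff(seq_len(L), i)
    head <- fit_clinic_head(F_[train, , , drop = FALSE], lab[train],
                            task = "classify", seed = seed + i, ...)
    probs[i, ] <- row_softmax(predict_head(head, F_[i, , , drop = FALSE]))
  }
  pred <- levels(lab)[max.col(probs, ties.method = "first")]
  res <- acc_auc(if (P == 2L) probs[, 2L] else probs, lab, predicted = pred)
  list(acc = res$acc, auc = res$auc, scores = probs, predicted = pred)
}
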
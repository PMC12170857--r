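# Shared fixtures. Heavy fits are computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# tiny two-slice dataset + graph for fast unit tests
tiny_setup <- function(seed = 5, n_spots = 40L, m = 60L, K_true = 2L) {
  sim <- simulate_slices(sim_config(L = 2L, n_spots = n_spots, m = m,
                                    K_true = K_true, markers_per_domain = 10L,
                                    seed = seed))
  slices <- lapply(sim$slices, normalize_log)
  ds <- suppressWarnings(
    assemble_dataset(slices, select_common_hvgs(slices, n_hvg = m)))
  intra <- lapply(seq_len(ds$L) - 1L, function(i)
    build_intra_edges(ds$S[ds$slice_of == i, , drop = FALSE], "knn", k = 4L))
  g <- unified_graph(intra, build_mnn_edges(ds, k_mnn = 3L, n_pcs = 10L),
                     ds$slice_of)
  list(sim = sim, ds = ds, graph = g)
}

# small training configuration for unit tests (full-size settings are
# exercised in the acceptance suite)
tiny_config <- function(seed = 1, ...) {
  train_config(pretrain_iters = 40L, outer_its = 2L, inner_epochs = 60L,
               hidden = 32L, min_epochs = 20L, plateau_window = 10L,
               seed = seed, ...)
}

# 24-slice clinical fixture: slice features built from a fast deterministic
# 2-D embedding (principal components) with the planted domains as cluster
# assignments, plus survival and class labels driven by domain 1
make_clinic_features <- function(seed = 101, L = 24L, n_spots = 120L,
                                 m = 300L, K = 4L, beta_sim = 3) {
  # case/control-style cohort: half the slices rich in the target niche,
  # half poor, so the planted hazard link is detectable at cohort scale
  alpha <- rbind(matrix(rep(c(5, rep(1, K - 1L)), each = L %/% 2L), L %/% 2L),
                 matrix(rep(c(0.3, rep(2, K - 1L)), each = L - L %/% 2L),
                        L - L %/% 2L))
  sim <- simulate_slices(sim_config(L = L, n_spots = n_spots, m = m,
                                    K_true = K, markers_per_domain = 40L,
                                    batch_scale = 0.2,
                                    composition_alpha = alpha, seed = seed))
  slices <- lapply(sim$slices, normalize_log)
  ds <- suppressWarnings(assemble_dataset(
    slices, select_common_hvgs(slices, n_hvg = m)))
  emb <- spniche:::pca_features(ds$X, 2L)
  domains <- unlist(sim$truth$domains)
  F_ <- slice_statistics(emb, domains, ds$slice_of, K)
  surv <- attach_survival(sim$truth, beta_sim = beta_sim, censoring = 0.1,
                          target_domain = 1L)
  cls <- attach_classes(sim$truth, target_domain = 1L)
  list(F_ = F_, surv = surv, cls = cls, target = 1L, ds = ds,
       truth = sim$truth)
}

# a naive double-loop GAT layer evaluation used as the equation oracle
gat_oracle <- function(h, A, params, activation = "elu") {
  A <- as.matrix(A)
  n <- nrow(h)
  Q <- params$Q
  acc <- matrix(0, n, params$d_out)
  lrelu <- function(x) if (x > 0) x else params$slope * x
  for (q in seq_len(Q)) {
    W <- params$W[[q]]
    a <- c(params$a_src[[q]], params$a_dst[[q]])
    Hq <- h %*% W
    for (i in seq_len(n)) {
      nbr <- which(A[i, ] != 0)
      logits <- vapply(nbr, function(j)
        lrelu(sum(a * c(Hq[i, ], Hq[j, ]))), 0)
      alpha <- exp(logits - max(logits))
      alpha <- alpha / sum(alpha)
      for (t in seq_along(nbr))
        acc[i, ] <- acc[i, ] + alpha[t] * Hq[nbr[t], ]
    }
  }
  pre <- acc / Q
  if (activation == "elu") ifelse(pre > 0, pre, exp(pmin(pre, 0)) - 1) else pre
}

# brute-force silhouette
silhouette_oracle <- function(X, lab) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(l)
      mean(D[i, lab == l]), 0))
    (b - a) / max(a, b)
  }, 0))
}

# brute-force concordance index
cindex_oracle <- function(s, t, e) {
  num <- 0; den <- 0
  n <- length(s)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || e[i] != 1) next
    if (t[j] > t[i] || (t[j] == t[i] && e[j] == 0)) {
      den <- den + 1
      num <- num + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
    }
  }
  num / den
}

# pair-counting ARI from the contingency table, written independently
ari_oracle <- function(a, b) {
  n <- length(a)
  ct <- as.matrix(table(a, b))
  ch2 <- function(x) choose(x, 2)
  sij <- sum(ch2(ct)); sa <- sum(ch2(rowSums(ct))); sb <- sum(ch2(colSums(ct)))
  e <- sa * sb / ch2(n)
  if ((sa + sb) / 2 == e) return(0)
  (sij - e) / ((sa + sb) / 2 - e)
}

nmi_oracle <- function(a, b) {
  n <- length(a)
  ct <- table(a, b)
  mi <- 0
  for (i in rownames(ct)) for (j in colnames(ct)) {
    nij <- ct[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(nij * n / (sum(ct[i, ]) * sum(ct[, j])))
  }
  h <- function(x) { p <- x / n; -sum(p[p > 0] * log(p[p > 0])) }
  mi / ((h(rowSums(ct)) + h(colSums(ct))) / 2)
}

auc_oracle <- function(s, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# direct per-spot kernel/entropy-bisection LISI oracle
lisi_oracle <- function(X, lab, perplexity = 30) {
  n <- nrow(X)
  lab <- as.integer(factor(lab))
  D <- as.matrix(dist(X))^2
  k <- min(3L * ceiling(perplexity), n - 1L)
  vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i], seq_len(n)[-i])
    nbr <- seq_len(n)[-i][ord[seq_len(k)]]
    d2 <- D[i, nbr]
    f <- function(beta) {
      w <- exp(-beta * d2)
      if (sum(w) == 0) return(-log(perplexity))
      p <- w / sum(w)
      -sum(p[p > 0] * log(p[p > 0])) - log(perplexity)
    }
    lo <- 1e-12; hi <- 1e12
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    beta <- sqrt(lo * hi)
    w <- exp(-beta * d2); p <- w / sum(w)
    1 / sum(vapply(unique(lab), function(l) sum(p[lab[nbr] == l]), 0)^2)
  }, 0)
}
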
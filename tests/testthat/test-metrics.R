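# Every metric is compared against an independent brute-force
# implementation (helpers) on randomized small instances, plus its
# analytic limiting cases.

test_that("ARI and NMI match pair-counting oracles on random partitions", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(a, b), ari_oracle(a, b), tolerance = 1e-8)
    expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-8)
  }
  a <- c(1, 1, 2, 2, 3)
  expect_equal(ari(a, a), 1)
  expect_equal(nmi(a, a), 1)
  # all-singletons vs all-one-cluster on n = 4: ARI = 0 by hand computation
  expect_equal(ari(1:4, rep(1, 4)), 0)
  expect_error(ari(1:3, 1:4), "length mismatch")
  # cross-check against an established implementation
  set.seed(42)
  a2 <- sample(1:3, 30, TRUE); b2 <- sample(1:3, 30, TRUE)
  expect_equal(ari(a2, b2), mclust::adjustedRandIndex(a2, b2),
               tolerance = 1e-12)
})

test_that("silhouette matches the brute-force oracle and its limits", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    X <- matrix(rnorm(2 * n), n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_asw(X, lab), silhouette_oracle(X, lab),
                 tolerance = 1e-12)
  }
  # far-separated pairs approach 1
  X <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  expect_gt(silhouette_asw(X, c(1, 1, 2, 2)), 0.98)
  # symmetric configuration with a(i) = b(i) gives 0
  Xs <- rbind(c(0, 0), c(1, 0), c(0.5, 0), c(0.5, 1))
  expect_error(silhouette_asw(Xs, rep(1, 4)), "2 distinct")
  # cross-check against the cluster package on one instance
  set.seed(44)
  X2 <- matrix(rnorm(40), 20)
  lab2 <- rep(1:2, each = 10)
  sil <- cluster::silhouette(lab2, dist(X2))
  expect_equal(silhouette_asw(X2, lab2), mean(sil[, 3]), tolerance = 1e-12)
})

test_that("F1 mixing score follows its closed form and monotonicity", {
  expect_equal(f1_mix(-1, 1), 1)
  expect_equal(f1_mix(0.3, -1), 0)
  expect_equal(f1_mix(0, 0), 0.5)
  # monotone: increasing in cluster ASW, decreasing in slice ASW
  grid <- seq(-0.9, 0.9, by = 0.3)
  for (s in grid) {
    v <- vapply(grid, function(c_) f1_mix(s, c_), 0)
    expect_true(all(diff(v) >= 0))
  }
  for (c_ in grid) {
    v <- vapply(grid, function(s) f1_mix(s, c_), 0)
    expect_true(all(diff(v) <= 0))
  }
})

test_that("LISI matches the kernel/entropy bisection oracle", {
  set.seed(45)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  lab <- rep(1:2, each = 50)
  r <- lisi(X, lab, perplexity = 15)
  expect_equal(r$scores, lisi_oracle(X, lab, 15), tolerance = 1e-6)
  expect_true(all(r$scores >= 1 - 1e-9 & r$scores <= 2 + 1e-9))
  # single label everywhere: scores exactly 1
  expect_equal(lisi(X, rep(1, 100), 15)$scores, rep(1, 100))
  # perfectly mixed labels in every neighbourhood approach 2
  Xm <- matrix(rnorm(200), 100)
  labm <- rep(1:2, 50)
  expect_gt(lisi(Xm, labm, 15)$mean, 1.7)
  expect_error(lisi(X[1:10, ], lab[1:10], 30), "exceed")
})

test_that("concordance index matches pair enumeration and survival::concordance", {
  set.seed(46)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    s <- rnorm(n); t <- rexp(n) + 0.1; e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) next
    expect_equal(c_index(s, t, e), cindex_oracle(s, t, e), tolerance = 1e-8)
  }
  # perfect anti-ordering
  t <- c(1, 2, 3, 4)
  expect_equal(c_index(c(4, 3, 2, 1), t, rep(1, 4)), 1)
  expect_equal(c_index(c(1, 2, 3, 4), t, rep(1, 4)), 0)
  expect_equal(c_index(rep(1, 4), t, rep(1, 4)), 0.5)
  # symmetry without score ties
  s <- c(0.3, -1, 2, 0.8, 0.1); tt <- c(2, 5, 1, 4, 3); e <- c(1, 0, 1, 1, 0)
  expect_equal(c_index(-s, tt, e), 1 - c_index(s, tt, e))
  # against survival's implementation
  cs <- survival::concordance(survival::Surv(tt, e) ~ s, reverse = TRUE)
  expect_equal(c_index(s, tt, e), unname(cs$concordance), tolerance = 1e-12)
  expect_error(c_index(1, 10, 0), "comparable")
})

test_that("accuracy and AUROC match rank-statistic hand computations", {
  set.seed(47)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(n)
    expect_equal(acc_auc(s, y)$auc, auc_oracle(s, y), tolerance = 1e-8)
  }
  # 4-slice toy with hand-set scores: 2 positives above both negatives
  expect_equal(acc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(acc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$acc, 1)
  # ties give 0.5 credit
  expect_equal(acc_auc(c(0.5, 0.5), c(1, 0))$auc, 0.5)
  expect_error(acc_auc(c(1, 2), c(1, 1)), "single-class")
  # against pROC on a larger instance
  set.seed(48)
  y2 <- rbinom(40, 1, 0.5); s2 <- rnorm(40) + y2
  expect_equal(acc_auc(s2, y2)$auc,
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE))),
               tolerance = 1e-12)
})
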
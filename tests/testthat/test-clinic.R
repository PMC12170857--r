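test_that("slice statistics reproduce hand arithmetic and fill rules", {
  # one slice, one cluster, spots at (0,0) and (2,2)
  emb <- rbind(c(0, 0), c(2, 2))
  F1 <- slice_statistics(emb, c(1L, 1L), c(0L, 0L), K = 1L)
  expect_equal(unname(F1[1, , 1]),
               c(1, 1, 1, 1, 2, 2, 0, 0, 1, 0))
  # two slices: P_within / P_other bookkeeping
  emb2 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 2), c(3, 3))
  asg <- c(1L, 1L, 2L, 1L, 2L, 2L)
  so <- c(0L, 0L, 0L, 1L, 1L, 1L)
  F2 <- slice_statistics(emb2, asg, so, K = 2L)
  expect_equal(unname(F2[1, "P_within", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(F2[1, "P_other", ]), c(1 / 3, 2 / 3))
  expect_equal(unname(F2[2, "P_within", ]), c(1 / 3, 2 / 3))
  # P_within rows sum to 1 when no cluster is empty
  expect_equal(rowSums(F2[, "P_within", ]), rep(1, 2))
  # cluster absent from a slice: ten zeros
  F3 <- slice_statistics(emb2, c(1L, 1L, 1L, 1L, 1L, 2L), so, K = 3L)
  expect_equal(unname(F3[1, , 2]), rep(0, 10))
  expect_equal(unname(F3[1, , 3]), rep(0, 10))
  # invariance to spot ordering
  perm <- sample(6)
  F4 <- slice_statistics(emb2[perm, ], asg[perm], so[perm], K = 2L)
  expect_equal(F4, F2)
})

test_that("attention pooling matches the loop oracle and softmax limits", {
  set.seed(51)
  K <- 3L
  F_i <- matrix(rnorm(10 * K), 10L)
  # identical attention vectors: uniform weights, mean over measures
  a_eq <- matrix(rep(rnorm(10 * K), each = 10L), 10L, byrow = FALSE)
  r_eq <- attention_pool(F_i, a_eq)
  expect_equal(r_eq$lambda, rep(0.1, 10L))
  expect_equal(r_eq$r, colMeans(F_i))
  # one dominant logit saturates to that measure's K-vector
  a_dom <- matrix(0, 10L, 10L * K); a_dom[4, ] <- 10
  v <- as.vector(t(F_i))
  if (sum(a_dom[4, ] * v) < 0) a_dom[4, ] <- -10
  r_dom <- attention_pool(F_i, a_dom)
  expect_gt(r_dom$lambda[4], 0.99)
  # random case equals a direct loop evaluation
  a <- matrix(rnorm(10 * 10 * K), 10L)
  got <- attention_pool(F_i, a)
  logits <- vapply(1:10, function(j) sum(a[j, ] * v), 0)
  lam <- exp(logits - max(logits)); lam <- lam / sum(lam)
  r_or <- rep(0, K)
  for (j in 1:10) r_or <- r_or + lam[j] * F_i[j, ]
  expect_equal(got$lambda, lam, tolerance = 1e-8)
  expect_equal(got$r, r_or, tolerance = 1e-8)
  expect_equal(sum(got$lambda), 1)
  # invariant to a constant added to all logits
  a_shift <- a + matrix(rep(rnorm(10 * K), each = 10L), 10L)
  expect_equal(attention_pool(F_i, a)$lambda,
               attention_pool(F_i, a_shift)$lambda, tolerance = 1e-8)
})

test_that("Cox partial likelihood handles risk sets, ties and censoring", {
  # single uncensored subject: 0
  expect_equal(cox_loss(0.7, 5, 1), 0)
  # two equal scores, both events, distinct times: log 2
  expect_equal(cox_loss(c(1, 1), c(2, 5), c(1, 1)), log(2))
  # 5 subjects with mixed censoring: hand-enumerated risk-set oracle
  s <- c(0.5, -0.2, 1.1, 0.0, -0.8)
  t <- c(3, 1, 4, 2, 5)
  e <- c(1, 0, 1, 1, 0)
  oracle <- 0
  for (i in which(e == 1)) {
    r <- which(t >= t[i])
    oracle <- oracle - (s[i] - log(sum(exp(s[r]))))
  }
  expect_equal(cox_loss(s, t, e), oracle, tolerance = 1e-12)
  # matches survival::coxph partial likelihood at fixed coefficients
  df <- data.frame(t = t, e = e, x = s)
  fit0 <- survival::coxph(survival::Surv(t, e) ~ x, data = df,
                          init = 1, control = survival::coxph.control(iter.max = 0))
  expect_equal(cox_loss(s, t, e), -fit0$loglik[2], tolerance = 1e-8)
  expect_error(cox_loss(c(1, 2), c(1, 2), c(0, 0)), "non-censored")
})

test_that("classification loss is the mean categorical cross-entropy", {
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(classify_loss(p, c(1L, 2L)), 0, tolerance = 1e-10)
  expect_equal(classify_loss(matrix(1 / 3, 4, 3), rep(1:3, length.out = 4)),
               log(3))
  set.seed(52)
  pr <- matrix(runif(12), 4); pr <- pr / rowSums(pr)
  lab <- c(1L, 3L, 2L, 1L)
  oracle <- -mean(log(pr[cbind(1:4, lab)]))
  expect_equal(classify_loss(pr, lab), oracle, tolerance = 1e-12)
})

test_that("head fitting recovers the hazard-driving cluster", {
  dat <- cache_fixture("clinic_sim", make_clinic_features(seed = 101))
  head <- fit_clinic_head(dat$F_, dat$surv, task = "cox", seed = 1)
  w <- head$cluster_weights
  expect_equal(which.max(w), dat$target)
  expect_gt(w[dat$target], 0)
  # attention weights are a probability vector per slice
  expect_equal(rowSums(head$lambda), rep(1, nrow(head$lambda)))
})

test_that("classification head separates classes driven by composition", {
  dat <- cache_fixture("clinic_sim", make_clinic_features(seed = 101))
  head <- fit_clinic_head(dat$F_, dat$cls$class, task = "classify", seed = 1)
  w <- head$cluster_weights   # P x K
  expect_equal(dim(w), c(2L, dim(dat$F_)[3]))
  contrib <- w[2, ] - w[1, ]
  expect_equal(which.max(abs(contrib)), dat$target)
})

test_that("cross-validated Cox discriminates informative from null labels", {
  dat <- cache_fixture("clinic_sim", make_clinic_features(seed = 101))
  cv <- cv_cox(dat$F_, dat$surv, folds = 7L, seed = 2)
  # the exponential-time generator caps attainable concordance near the
  # true-hazard level (~0.67 on this cohort); the fitted head must come
  # close to that ceiling and clearly beat the permuted-label null
  expect_gte(cv$median_cindex, 0.6)
  expect_length(cv$hr, nrow(dat$surv))
  nulls <- vapply(1:3, function(p) {
    perm <- withr::with_seed(98 + p, dat$surv[sample(nrow(dat$surv)), ])
    cv_cox(dat$F_, perm, folds = 7L, seed = 2)$median_cindex
  }, 0)
  expect_gte(mean(nulls), 0.3)
  expect_lte(mean(nulls), 0.7)
  expect_error(cv_cox(dat$F_, dat$surv, folds = 24L, seed = 1),
               ">= 2 slices")
})

test_that("shared UMAP embedding is seeded and separates latent blobs", {
  set.seed(53)
  z <- rbind(matrix(rnorm(200, 0), 40), matrix(rnorm(200, 8), 40))
  e1 <- embed_umap(z, seed = 5)
  expect_equal(dim(e1), c(80L, 2L))
  expect_identical(e1, embed_umap(z, seed = 5))
  between <- sqrt(sum((colMeans(e1[1:40, ]) - colMeans(e1[41:80, ]))^2))
  within <- mean(sqrt(rowSums((e1[1:40, ] -
    matrix(colMeans(e1[1:40, ]), 40, 2, byrow = TRUE))^2)))
  expect_gt(between, within)
  expect_error(embed_umap(z[1:5, ]), "at least 10")
})
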
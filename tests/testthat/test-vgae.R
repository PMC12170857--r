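test_that("expression decoder applies per-slice batch normalization", {
  set.seed(31)
  n <- 12L; d <- 3L; m <- 5L; L <- 2L
  z <- matrix(rnorm(n * d), n)
  slice_of <- rep(0:1, each = 6L)
  dec <- list(W = matrix(rnorm(m * d), m), b = rnorm(m),
              gamma = matrix(rnorm(L * m), L), beta = matrix(rnorm(L * m), L),
              eps = 1e-5)
  out <- decode_expression(z, slice_of, dec)
  # hand-rolled per-slice standardization oracle
  h <- dec$W %*% t(z) + dec$b
  oracle <- h
  for (i in 1:L) {
    cols <- which(slice_of == i - 1L)
    hi <- h[, cols]
    mu <- rowMeans(hi); v <- rowMeans(hi^2) - mu^2
    oracle[, cols] <- dec$gamma[i, ] * (hi - mu) / sqrt(v + dec$eps) +
      dec$beta[i, ]
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # gamma = 1, beta = 0 on already-standardized h reproduces h (up to eps)
  dec2 <- dec; dec2$gamma[] <- 1; dec2$beta[] <- 0
  out2 <- decode_expression(z, slice_of, dec2)
  for (i in 1:L) {
    cols <- which(slice_of == i - 1L)
    expect_equal(unname(rowMeans(out2[, cols])), rep(0, m), tolerance = 1e-8)
  }
  # gamma = 0 broadcasts beta
  dec3 <- dec; dec3$gamma[] <- 0
  out3 <- decode_expression(z, slice_of, dec3)
  expect_equal(out3[, 1], dec$beta[1, ])
  expect_equal(out3[, 12], dec$beta[2, ])
})

test_that("graph decoder is an elementwise sigmoid of inner products", {
  z <- rbind(c(1, 0), c(0, 1), c(2, 2))
  Ap <- decode_graph(z)
  expect_equal(Ap[1, 2], 0.5)                       # orthogonal
  expect_equal(Ap[1, 3], 1 / (1 + exp(-2)))         # hand arithmetic
  expect_equal(Ap[2, 3], 1 / (1 + exp(-2)))
  expect_true(isSymmetric(Ap))
  expect_true(all(Ap > 0 & Ap < 1))
  # saturation for identical large vectors
  zb <- rbind(c(10, 10), c(10, 10))
  expect_gt(decode_graph(zb)[1, 2], 1 - 1e-10)
  # invariant under joint orthogonal rotation
  set.seed(32)
  z3 <- matrix(rnorm(12), 4)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(decode_graph(z3), decode_graph(z3 %*% R))
})

test_that("reconstruction losses match their definitions", {
  set.seed(33)
  # expression: zero iff equal; all-ones difference gives 1 per convention
  X <- matrix(rnorm(20), 4)
  expect_equal(loss_expression(X, X, rep(0L, 5L)), 0)
  expect_equal(loss_expression(X, X + 1, rep(0L, 5L)), 1)
  # random case against a loop oracle over slices
  Xp <- X + matrix(rnorm(20), 4)
  so <- c(0L, 0L, 0L, 1L, 1L)
  oracle <- mean(c(mean((X[, 1:3] - Xp[, 1:3])^2),
                   mean((X[, 4:5] - Xp[, 4:5])^2)))
  expect_equal(loss_expression(X, Xp, so), oracle)
  # adjacency: A' == 0.5 gives log 2; clipped-exact reconstruction ~ 0
  A <- diag(4); A[1, 2] <- A[2, 1] <- 1
  expect_equal(loss_adjacency(A, matrix(0.5, 4, 4)), log(2))
  Ac <- pmin(pmax(A, 1e-7), 1 - 1e-7)
  expect_lt(loss_adjacency(A, Ac), 1e-5)
  # 6x6 random case equals the full-sum oracle
  z <- matrix(rnorm(12), 6)
  A6 <- (as.matrix(dist(z)) < 1.5) * 1
  Ap <- decode_graph(z)
  Apc <- pmin(pmax(Ap, 1e-7), 1 - 1e-7)
  oracle6 <- -sum(A6 * log(Apc) + (1 - A6) * log(1 - Apc)) / 36
  expect_equal(loss_adjacency(A6, Ap), oracle6, tolerance = 1e-10)
})

test_that("mixture responsibilities follow the component likelihoods", {
  # K = 1: all ones
  g1 <- gmm_params(1L, matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(gmm_responsibilities(matrix(rnorm(10), 5), g1),
               matrix(1, 5, 1))
  # point at a component mean, far from the other
  g2 <- gmm_params(2L, rbind(c(0, 0), c(50, 50)),
                   matrix(0, 2, 2))
  r <- gmm_responsibilities(rbind(c(0, 0)), g2)
  expect_gt(r[1, 1], 1 - 1e-10)
  # n = 5, K = 2 toy values match direct density-ratio arithmetic
  set.seed(34)
  z <- matrix(rnorm(10), 5)
  gm <- gmm_params(2L, rbind(c(-1, 0), c(1, 1)),
                   rbind(c(0.1, -0.2), c(0.3, 0)))
  r2 <- gmm_responsibilities(z, gm)
  dens <- function(zu, c) {
    s <- exp(gm$logvar[c, ])
    prod(exp(-(zu - gm$mu[c, ])^2 / (2 * s)) / sqrt(2 * pi * s))
  }
  for (u in 1:5) {
    d1 <- dens(z[u, ], 1); d2 <- dens(z[u, ], 2)
    expect_equal(r2[u, ], c(d1, d2) / (d1 + d2), tolerance = 1e-10)
  }
  expect_equal(rowSums(r2), rep(1, 5))
})

test_that("KL to the mixture prior hits its closed-form limits", {
  # matched single-component prior: zero
  set.seed(35)
  mu <- matrix(rnorm(8), 4); lv <- matrix(rnorm(8, 0, 0.3), 4)
  for (u in 1:4) {
    g <- gmm_params(1L, mu[u, , drop = FALSE], lv[u, , drop = FALSE])
    expect_equal(loss_kl(mu[u, , drop = FALSE], lv[u, , drop = FALSE],
                         matrix(1, 1, 1), g), 0, tolerance = 1e-12)
  }
  # uniform responsibilities zero the categorical term: remaining value
  # equals the weighted Gaussian-KL sum oracle
  gm <- gmm_params(2L, rbind(c(0, 0), c(2, -1)), rbind(c(0, 0), c(0.5, -0.5)))
  resp <- matrix(0.5, 4, 2)
  kl_gauss <- function(m1, lv1, m2, lv2)
    0.5 * sum(lv2 - lv1 + (exp(lv1) + (m1 - m2)^2) / exp(lv2) - 1)
  oracle <- sum(vapply(1:4, function(u)
    0.5 * kl_gauss(mu[u, ], lv[u, ], gm$mu[1, ], gm$logvar[1, ]) +
    0.5 * kl_gauss(mu[u, ], lv[u, ], gm$mu[2, ], gm$logvar[2, ]), 0))
  expect_equal(loss_kl(mu, lv, resp, gm), oracle, tolerance = 1e-10)
  expect_gte(loss_kl(mu, lv, resp, gm), 0)
  # skewed responsibilities: categorical entropy term included
  resp2 <- cbind(rep(0.9, 4), rep(0.1, 4))
  oracle2 <- sum(vapply(1:4, function(u)
    0.9 * kl_gauss(mu[u, ], lv[u, ], gm$mu[1, ], gm$logvar[1, ]) +
    0.1 * kl_gauss(mu[u, ], lv[u, ], gm$mu[2, ], gm$logvar[2, ]), 0)) +
    4 * (0.9 * log(0.9 * 2) + 0.1 * log(0.1 * 2))
  expect_equal(loss_kl(mu, lv, resp2, gm), oracle2, tolerance = 1e-10)
})

test_that("the total loss is the weighted sum of its parts", {
  expect_equal(loss_total(list(exp = 5, adj = 9, kl = 4),
                          list(delta = 0, phi = 0)), 5)
  expect_equal(loss_total(list(exp = 1, adj = 1, kl = 1),
                          list(delta = 2, phi = 3)), 6)
  set.seed(36)
  p <- as.list(abs(rnorm(3))); names(p) <- c("exp", "adj", "kl")
  w <- list(delta = abs(rnorm(1)), phi = abs(rnorm(1)))
  expect_equal(loss_total(p, w), p$exp + w$delta * p$adj + w$phi * p$kl)
})
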
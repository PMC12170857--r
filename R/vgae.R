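# Variational graph autoencoder with a mixture-of-Gaussians latent prior.
#
# Encoder: two stacked multi-head GAT layers (hidden 512, latent 10); the
# second stage has two parallel heads producing the posterior mean and
# log-variance. Decoder: one shared linear map back to gene space followed
# by slice-specific batch normalization (scale/shift per slice), plus an
# inner-product graph decoder. Losses: per-slice MSE on expression,
# full-matrix cross-entropy on the adjacency, and the mean-field KL to the
# MoG prior.

#' Initialize the VGAE model state
#'
#' @param m Number of genes (input features).
#' @param L Number of slices.
#' @param d Latent dimension.
#' @param hidden Hidden layer width.
#' @param Q Attention heads per layer.
#' @param eps Batch-norm constant.
#' @param seed Seed for parameter initialization.
#' @return A `vgae_model` list: `enc` (three GAT parameter sets: `layer1`,
#'   `mu`, `lv`), `dec` (shared `W` (m x d), `b`, per-slice `gamma`, `beta`
#'   (L x m), `eps`), `gmm` (NULL until [init_gmm()]), and `dims`.
#' @export
init_model <- function(m, L, d = 10L, hidden = 512L, Q = 3L,
                       eps = 1e-5, seed = 1L) {
  with_seed(seed, {
    enc <- list(layer1 = init_gat_layer(m, hidden, Q),
                mu = init_gat_layer(hidden, d, Q),
                lv = init_gat_layer(hidden, d, Q))
    lim <- sqrt(6 / (m + d))
    dec <- list(W = matrix(runif(m * d, -lim, lim), m, d),
                b = numeric(m),
                gamma = matrix(1, L, m), beta = matrix(0, L, m),
                eps = eps)
    structure(list(enc = enc, dec = dec, gmm = NULL,
                   dims = list(m = m, L = L, d = d, hidden = hidden, Q = Q)),
              class = "vgae_model")
  })
}

#' Encode spots into the latent space
#'
#' Runs the two-layer GAT encoder; in training mode the latent is
#' reparameterized as `z = mu + exp(logvar/2) * eta` with standard-normal
#' `eta` drawn from `seed`; in evaluation mode `z = mu`.
#'
#' @param X Genes x spots matrix.
#' @param A Adjacency with self-loops (or a `unified_graph`).
#' @param enc Encoder parameter list from [init_model()] (`model$enc`).
#' @param seed Seed for the reparameterization noise.
#' @param eval_mode If `TRUE`, return `z = mu` without sampling.
#' @return List with `mu`, `logvar`, `z` (all n x d).
#' @export
encode <- function(X, A, enc, seed = 1L, eval_mode = FALSE) {
  edges <- edge_index(A)
  h1 <- gat_fwd(t(X), edges, enc$layer1, "elu")
  assert_finite(h1$out, "encoder layer 1")
  mu <- gat_fwd(h1$out, edges, enc$mu, "identity")$out
  lv <- gat_fwd(h1$out, edges, enc$lv, "identity")$out
  assert_finite(mu, "encoder layer 2 (mu)")
  assert_finite(lv, "encoder layer 2 (logvar)")
  lv <- pmin(pmax(lv, -10), 10)
  z <- if (eval_mode) mu else
    mu + exp(lv / 2) * with_seed(seed, matrix(rnorm(length(mu)), nrow(mu)))
  list(mu = mu, logvar = lv, z = z)
}

# batch-norm decode, gene-major internal version: returns m x n matrices so
# per-slice gene statistics recycle down columns (fast, no sweeps)
decode_bn <- function(z, slice_index, dec) {
  h <- tcrossprod(dec$W, z) + dec$b      # m x n, b recycles down columns
  out <- h; cache <- vector("list", max(slice_index))
  for (i in sort(unique(slice_index))) {
    cols <- which(slice_index == i)
    hi <- h[, cols, drop = FALSE]
    mu_i <- rowMeans(hi)
    var_i <- pmax(rowMeans(hi^2) - mu_i^2, 0)
    den <- sqrt(var_i + dec$eps)
    xhat <- (hi - mu_i) / den
    out[, cols] <- dec$gamma[i, ] * xhat + dec$beta[i, ]
    cache[[i]] <- list(cols = cols, xhat = xhat, den = den)
  }
  list(out = out, h = h, cache = cache)
}

# dY is m x n (gene-major)
decode_bn_bwd <- function(dY, z, dec, cache) {
  dH <- dY * 0
  dgamma <- dec$gamma * 0; dbeta <- dec$beta * 0
  for (i in seq_along(cache)) {
    cc <- cache[[i]]
    if (is.null(cc)) next
    dy <- dY[, cc$cols, drop = FALSE]
    dgamma[i, ] <- rowSums(dy * cc$xhat)
    dbeta[i, ] <- rowSums(dy)
    dxh <- dec$gamma[i, ] * dy
    dH[, cc$cols] <- (dxh - rowMeans(dxh) -
                        cc$xhat * rowMeans(dxh * cc$xhat)) / cc$den
  }
  dW <- dH %*% z                         # m x d
  db <- rowSums(dH)
  dz <- crossprod(dH, dec$W)             # n x d
  list(dz = dz, dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
}

#' Decode expression with slice-specific batch normalization
#'
#' `h = W z + b` (shared across slices), then within each slice the decoded
#' profiles are standardized by that slice's batch statistics and rescaled
#' by slice-specific `gamma`/`beta`.
#'
#' @param z Latent matrix, n x d.
#' @param slice_of 0-based slice index per spot.
#' @param dec Decoder parameters (`model$dec`).
#' @return Reconstructed genes x spots matrix.
#' @export
decode_expression <- function(z, slice_of, dec) {
  decode_bn(as.matrix(z), slice_of + 1L, dec)$out
}

#' Inner-product graph decoder
#'
#' @param z Latent matrix, n x d.
#' @return Symmetric n x n matrix `sigmoid(z_u . z_v)` with values in (0,1).
#' @export
decode_graph <- function(z) {
  1 / (1 + exp(-tcrossprod(as.matrix(z))))
}

#' Per-slice mean-squared reconstruction loss
#'
#' Average over slices of the mean squared elementwise difference between
#' the slice's input and reconstruction.
#'
#' @param X,X_prime Genes x spots matrices of equal shape.
#' @param slice_of 0-based slice index per spot.
#' @return Non-negative scalar; 0 iff `X_prime == X`.
#' @export
loss_expression <- function(X, X_prime, slice_of) {
  stopifnot(all(dim(X) == dim(X_prime)))
  sl <- sort(unique(slice_of))
  mean(vapply(sl, function(i)
    mean((X[, slice_of == i, drop = FALSE] -
            X_prime[, slice_of == i, drop = FALSE])^2), 0))
}

#' Cross-entropy loss between observed and reconstructed adjacency
#'
#' Full-matrix mean binary cross-entropy over all n^2 ordered pairs, with
#' probability clipping. Above `sample_threshold` spots an unbiased
#' estimate is used: all positive pairs plus an equal-count uniform sample
#' of negatives, rescaled to the full-sum convention.
#'
#' @param A Binary adjacency including self-loops (sparse or dense).
#' @param A_prime Matrix of edge probabilities in (0,1), or the latent `z`
#'   (n x d, detected by shape) from which probabilities are computed
#'   pair-by-pair without materializing n x n.
#' @param clip Probability clipping constant.
#' @param sample_threshold Spot count above which the sampled estimate is
#'   used.
#' @param seed Seed for the negative sample.
#' @return Non-negative scalar.
#' @export
loss_adjacency <- function(A, A_prime, clip = 1e-7, sample_threshold = 5000L,
                           seed = 1L) {
  n <- nrow(A)
  ce <- function(a, p) {
    p <- pmin(pmax(p, clip), 1 - clip)
    -(a * log(p) + (1 - a) * log(1 - p))
  }
  if (n <= sample_threshold) {
    Ad <- as.matrix(A)
    return(sum(ce(Ad, as.matrix(A_prime))) / (n * n))
  }
  # sampled estimate (A_prime must be the latent z here to stay scalable)
  z <- as.matrix(A_prime)
  Ts <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  pi_ <- Ts@i + 1L; pj <- Ts@j + 1L
  npos <- length(pi_)
  neg <- with_seed(seed, cbind(sample.int(n, npos, replace = TRUE),
                               sample.int(n, npos, replace = TRUE)))
  sig <- function(i, j) 1 / (1 + exp(-rowSums(z[i, , drop = FALSE] *
                                                z[j, , drop = FALSE])))
  ce_pos <- mean(ce(1, sig(pi_, pj)))
  ce_neg <- mean(ce(0, sig(neg[, 1L], neg[, 2L])))
  (npos * ce_pos + (n * n - npos) * ce_neg) / (n * n)
}

#' Mixture-of-Gaussians initialization container
#'
#' @param K Component count.
#' @param mu K x d component means.
#' @param logvar K x d log of component diagonal variances.
#' @return A `gmm_params` list; mixing weights are fixed uniform 1/K.
#' @export
gmm_params <- function(K, mu, logvar) {
  stopifnot(nrow(mu) == K, all(dim(mu) == dim(logvar)))
  structure(list(K = as.integer(K), pi = rep(1 / K, K),
                 mu = mu, logvar = logvar), class = "gmm_params")
}

#' Posterior responsibilities of mixture components
#'
#' `q(c|z_u)` proportional to `pi_c N(z_u; u_c, diag sigma2_c)`, computed in
#' log-space; rows sum to 1.
#'
#' @param z n x d matrix of latent positions (typically the posterior mean).
#' @param gmm A `gmm_params`.
#' @return n x K responsibility matrix.
#' @export
gmm_responsibilities <- function(z, gmm) {
  z <- as.matrix(z)
  n <- nrow(z); d <- ncol(z)
  lg <- matrix(0, n, gmm$K)
  for (c in seq_len(gmm$K)) {
    s <- exp(gmm$logvar[c, ])
    diff2 <- sweep(z, 2L, gmm$mu[c, ])^2
    lg[, c] <- log(gmm$pi[c]) - 0.5 * (d * log(2 * pi) +
      sum(gmm$logvar[c, ]) + rowSums(sweep(diff2, 2L, s, "/")))
  }
  row_softmax(lg)
}

#' KL divergence from the MoG prior to the variational posterior
#'
#' Mean-field factorization `q(z,c|X,A) = q(z|X,A) q(c|X,A)`: the sum over
#' spots of the responsibility-weighted Gaussian KLs plus the categorical
#' term `sum_c gamma_c log(gamma_c K)`.
#'
#' @param mu,logvar Posterior moments, n x d.
#' @param resp Responsibilities, n x K (e.g. [gmm_responsibilities()]).
#' @param gmm A `gmm_params`.
#' @return Non-negative scalar.
#' @export
loss_kl <- function(mu, logvar, resp, gmm) {
  kl_parts(mu, logvar, resp, gmm)$value
}

# value + all gradients of the KL term (resp treated as constant)
kl_parts <- function(mu, logvar, resp, gmm) {
  n <- nrow(mu); d <- ncol(mu)
  ev <- exp(logvar)
  dmu <- mu * 0; dlv <- mu * 0
  dgmu <- gmm$mu * 0; dglv <- gmm$logvar * 0
  value <- 0
  for (c in seq_len(gmm$K)) {
    g <- resp[, c]
    s <- exp(gmm$logvar[c, ])
    diff <- sweep(mu, 2L, gmm$mu[c, ])
    klc <- 0.5 * (sum(gmm$logvar[c, ]) - rowSums(logvar) +
                    rowSums(sweep(ev + diff^2, 2L, s, "/")) - d)
    value <- value + sum(g * klc)
    dmu <- dmu + g * sweep(diff, 2L, s, "/")
    dlv <- dlv + g * 0.5 * (sweep(ev, 2L, s, "/") - 1)
    dgmu[c, ] <- -colSums(g * diff) / s
    dglv[c, ] <- 0.5 * colSums(g * (1 - sweep(ev + diff^2, 2L, s, "/")))
  }
  ent <- resp * log(pmax(resp, 1e-12) * gmm$K)
  value <- value + sum(ent)
  list(value = value, dmu = dmu, dlv = dlv, dgmm_mu = dgmu,
       dgmm_logvar = dglv)
}

#' Weighted total unsupervised loss
#'
#' @param parts List with `exp`, `adj`, `kl` scalars.
#' @param weights List with `delta` (adjacency weight) and `phi` (KL
#'   weight), both >= 0.
#' @return `exp + delta*adj + phi*kl`.
#' @export
loss_total <- function(parts, weights = list(delta = 1, phi = 1)) {
  stopifnot(weights$delta >= 0, weights$phi >= 0)
  parts$exp + weights$delta * parts$adj + weights$phi * (parts$kl %||% 0)
}
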
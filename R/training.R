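# Three-phase optimization: pretrain (reconstruction only), GMM
# initialization from the preliminary latent, then the dynamic loop that
# alternates gradient training with cross-component edge pruning.

#' Training configuration
#'
#' @param pretrain_iters Iterations of reconstruction-only pretraining.
#' @param outer_its Number of prune cycles (`it` runs `0..outer_its-1`).
#' @param inner_epochs Gradient-step budget per prune cycle.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay on encoder/decoder weights.
#' @param delta,phi Adjacency-loss and KL-loss weights.
#' @param hidden,d,Q Encoder architecture (hidden width, latent dim, heads).
#' @param fixed_graph If `TRUE`, pruning is skipped (fixed-graph ablation).
#' @param plateau_tol,plateau_window,min_epochs Inner-loop convergence rule:
#'   stop a cycle early once the windowed-mean loss improves by less than
#'   `plateau_tol` (relative) over `plateau_window` epochs, after at least
#'   `min_epochs`.
#' @param seed Master seed; fans out to init, sampling, and GMM stages.
#' @return A `train_config` list.
#' @export
train_config <- function(pretrain_iters = 300L, outer_its = 3L,
                         inner_epochs = 300L, lr = 1e-3,
                         weight_decay = 5e-4, delta = 1, phi = 1,
                         hidden = 512L, d = 10L, Q = 3L,
                         fixed_graph = FALSE, plateau_tol = 1e-4,
                         plateau_window = 50L, min_epochs = 100L,
                         seed = 1L) {
  stopifnot(pretrain_iters >= 0, outer_its >= 1, inner_epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

# ---- parameter plumbing -------------------------------------------------

trainable_params <- function(model) {
  ps <- list()
  for (lay in c("layer1", "mu", "lv")) {
    lp <- model$enc[[lay]]
    for (q in seq_len(lp$Q)) {
      ps[[paste0(lay, ".W", q)]] <- lp$W[[q]]
      ps[[paste0(lay, ".asrc", q)]] <- lp$a_src[[q]]
      ps[[paste0(lay, ".adst", q)]] <- lp$a_dst[[q]]
    }
  }
  ps$dec.W <- model$dec$W; ps$dec.b <- model$dec$b
  ps$dec.gamma <- model$dec$gamma; ps$dec.beta <- model$dec$beta
  if (!is.null(model$gmm)) {
    ps$gmm.mu <- model$gmm$mu; ps$gmm.logvar <- model$gmm$logvar
  }
  ps
}

set_params <- function(model, ps) {
  for (lay in c("layer1", "mu", "lv")) {
    for (q in seq_len(model$enc[[lay]]$Q)) {
      model$enc[[lay]]$W[[q]] <- ps[[paste0(lay, ".W", q)]]
      model$enc[[lay]]$a_src[[q]] <- ps[[paste0(lay, ".asrc", q)]]
      model$enc[[lay]]$a_dst[[q]] <- ps[[paste0(lay, ".adst", q)]]
    }
  }
  model$dec$W <- ps$dec.W; model$dec$b <- ps$dec.b
  model$dec$gamma <- ps$dec.gamma; model$dec$beta <- ps$dec.beta
  if (!is.null(model$gmm)) {
    model$gmm$mu <- ps$gmm.mu; model$gmm$logvar <- ps$gmm.logvar
  }
  model
}

adam_init <- function(ps) {
  list(m = lapply(ps, function(p) p * 0), v = lapply(ps, function(p) p * 0),
       t = 0L)
}

adam_step <- function(ps, gs, st, lr, weight_decay = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t; b2t <- 1 - beta2^st$t
  for (nm in names(ps)) {
    g <- gs[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("\\.W", nm)) g <- g + weight_decay * ps[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    ps[[nm]] <- ps[[nm]] - lr * (st$m[[nm]] / b1t) /
      (sqrt(st$v[[nm]] / b2t) + eps)
  }
  list(ps = ps, st = st)
}

# ---- one full-batch gradient step ---------------------------------------

# Xt: spots x genes; Xm: genes x spots (same data); A_dense: n x n binary
# with self loops; edges: edge_index
train_step <- function(Xt, Xm, edges, A_dense, slice_index, model, cfg,
                       use_kl, eta) {
  n <- nrow(Xt); L <- model$dims$L
  h1 <- gat_fwd(Xt, edges, model$enc$layer1, "elu")
  cmu <- gat_fwd(h1$out, edges, model$enc$mu, "identity")
  clv <- gat_fwd(h1$out, edges, model$enc$lv, "identity")
  mu <- cmu$out
  lv_raw <- clv$out
  lv <- pmin(pmax(lv_raw, -10), 10)
  lvmask <- (lv_raw > -10) & (lv_raw < 10)
  if (!all(is.finite(mu)) || !all(is.finite(lv)))
    stop("non-finite activations in encoder layer 2", call. = FALSE)
  sig <- exp(lv / 2)
  z <- mu + sig * eta

  # expression reconstruction: fused decode + per-slice BN + loss + grads
  n_of <- tabulate(slice_index, L)
  w_col <- 1 / (L * n_of[slice_index] * nrow(Xm))     # per-spot weights
  dbk <- cpp_decode_loss(z, model$dec$W, model$dec$b, model$dec$gamma,
                         model$dec$beta, model$dec$eps, slice_index, L,
                         Xm, w_col)
  l_exp <- dbk$loss

  # adjacency reconstruction (full matrix), loss and gradient in one pass
  adj <- cpp_adj_loss(z, A_dense)
  l_adj <- adj$loss
  dz_adj <- adj$dz

  dz <- dbk$dz + cfg$delta * dz_adj
  dmu <- dz
  dlv <- dz * eta * 0.5 * sig

  parts <- list(exp = l_exp, adj = l_adj, kl = 0)
  gg_mu <- NULL; gg_lv <- NULL
  if (use_kl && !is.null(model$gmm)) {
    # KL is summed over spots and latent dims; the expression loss is a
    # per-element mean. Normalizing the KL by n*m keeps the two terms on
    # the sum-convention balance (a pure phi rescaling).
    ks <- 1 / (n * nrow(Xm))
    resp <- gmm_responsibilities(mu, model$gmm)
    kp <- kl_parts(mu, lv, resp, model$gmm)
    parts$kl <- ks * kp$value
    dmu <- dmu + cfg$phi * ks * kp$dmu
    dlv <- dlv + cfg$phi * ks * kp$dlv
    gg_mu <- cfg$phi * ks * kp$dgmm_mu
    gg_lv <- cfg$phi * ks * kp$dgmm_logvar
  }
  dlv <- dlv * lvmask

  bmu <- gat_bwd(dmu, cmu, need_dh = TRUE)
  blv <- gat_bwd(dlv, clv, need_dh = TRUE)
  dh1 <- (bmu$dh + blv$dh) * h1$act_grad
  b1 <- gat_bwd_from_pre(dh1, h1)

  gs <- list()
  pack <- function(lay, bk) {
    for (q in seq_along(bk$W)) {
      gs[[paste0(lay, ".W", q)]] <<- bk$W[[q]]
      gs[[paste0(lay, ".asrc", q)]] <<- bk$a_src[[q]]
      gs[[paste0(lay, ".adst", q)]] <<- bk$a_dst[[q]]
    }
  }
  pack("layer1", b1); pack("mu", bmu); pack("lv", blv)
  gs$dec.W <- dbk$dW; gs$dec.b <- drop(dbk$db)
  gs$dec.gamma <- dbk$dgamma; gs$dec.beta <- dbk$dbeta
  if (!is.null(gg_mu)) { gs$gmm.mu <- gg_mu; gs$gmm.logvar <- gg_lv }
  list(loss = loss_total(parts, list(delta = cfg$delta, phi = cfg$phi)),
       parts = parts, grads = gs, mu = mu)
}

# layer-1 backward where the ELU chain rule was already applied to dpre
gat_bwd_from_pre <- function(dpre_times_act, cache) {
  cache$activation <- "identity"
  gat_bwd(dpre_times_act, cache, need_dh = FALSE)
}

run_epochs <- function(Xt, Xm, edges, A_dense, slice_index, model, cfg, use_kl,
                       n_epochs, ps, st, seed, loss_history) {
  n <- nrow(Xt); d <- model$dims$d
  smoothed <- c()
  for (ep in seq_len(n_epochs)) {
    eta <- with_seed(seed + ep, matrix(rnorm(n * d), n, d))
    stp <- tryCatch(
      train_step(Xt, Xm, edges, A_dense, slice_index, model, cfg, use_kl, eta),
      error = function(e)
        stop(sprintf("training diverged at step %d: %s", ep,
                     conditionMessage(e)), call. = FALSE))
    if (!is.finite(stp$loss))
      stop(sprintf("training diverged at step %d (non-finite loss)", ep),
           call. = FALSE)
    upd <- adam_step(ps, stp$grads, st, cfg$lr, cfg$weight_decay)
    ps <- upd$ps; st <- upd$st
    model <- set_params(model, ps)
    loss_history <- c(loss_history, stp$loss)
    # plateau early stop on the windowed mean
    k <- length(loss_history)
    w <- cfg$plateau_window
    if (ep >= max(cfg$min_epochs, 2 * w)) {
      recent <- mean(loss_history[(k - w + 1L):k])
      older <- mean(loss_history[(k - 2L * w + 1L):(k - w)])
      if (is.finite(recent) && abs(older - recent) <
          cfg$plateau_tol * abs(older)) break
    }
  }
  list(model = model, ps = ps, st = st, loss_history = loss_history)
}

#' Pretrain the VGAE without the mixture regularizer
#'
#' Optimizes expression + adjacency reconstruction only, for
#' `cfg$pretrain_iters` full-batch steps, and returns the preliminary
#' evaluation-mode latent.
#'
#' @param dataset A `multislice_dataset`.
#' @param graph A `unified_graph` at `it = 0`.
#' @param cfg A [train_config()].
#' @param model Optional pre-initialized model (default: fresh
#'   [init_model()] from `cfg$seed`).
#' @return List with `model`, `z0` (n x d), `loss_history`, and internal
#'   optimizer state for continued training.
#' @export
pretrain <- function(dataset, graph, cfg = train_config(), model = NULL) {
  stopifnot(inherits(dataset, "multislice_dataset"),
            inherits(graph, "unified_graph"))
  seeds <- derive_seeds(cfg$seed, 4L)
  m <- nrow(dataset$X); n <- ncol(dataset$X)
  model <- model %||% init_model(m, dataset$L, d = cfg$d,
                                 hidden = cfg$hidden, Q = cfg$Q,
                                 seed = seeds[1L])
  Xt <- t(dataset$X)
  Xm <- dataset$X
  edges <- edge_index(graph)
  A_dense <- as.matrix(graph_adjacency(graph, self_loops = TRUE))
  slice_index <- dataset$slice_of + 1L
  ps <- trainable_params(model)
  st <- adam_init(ps)
  hist <- numeric(0)
  if (cfg$pretrain_iters > 0) {
    # pretraining ignores the plateau rule: a fixed short budget
    cfg2 <- cfg; cfg2$min_epochs <- cfg$pretrain_iters
    r <- run_epochs(Xt, Xm, edges, A_dense, slice_index, model, cfg2,
                    use_kl = FALSE, n_epochs = cfg$pretrain_iters, ps, st,
                    seed = seeds[2L], loss_history = hist)
    model <- r$model; ps <- r$ps; st <- r$st; hist <- r$loss_history
  }
  z0 <- encode(dataset$X, graph, model$enc, eval_mode = TRUE)$mu
  list(model = model, z0 = z0, loss_history = hist, opt_state = st,
       seeds = seeds)
}

#' Initialize mixture parameters from a preliminary latent
#'
#' Fits a diagonal-covariance Gaussian mixture to `z0` by EM and sets the
#' component means and variances to the fitted values; mixing weights stay
#' uniform.
#'
#' @param z0 n x d latent matrix.
#' @param K Number of components (>= 1).
#' @param seed Seed for the EM initialization.
#' @param var_floor Lower bound on component variances.
#' @return A [gmm_params()].
#' @export
init_gmm <- function(z0, K, seed = 1L, var_floor = 1e-4) {
  z0 <- as.matrix(z0)
  d <- ncol(z0)
  if (K == 1L)
    return(gmm_params(1L, matrix(colMeans(z0), 1L),
                      matrix(log(pmax(apply(z0, 2L, var), var_floor)), 1L)))
  fit <- with_seed(seed, tryCatch(
    mclust::Mclust(z0, G = K, modelNames = "VVI", verbose = FALSE),
    error = function(e) NULL))
  if (!is.null(fit) && !is.null(fit$parameters$mean)) {
    muK <- t(fit$parameters$mean)
    varK <- t(apply(fit$parameters$variance$sigma, 3L, diag))
  } else {
    # k-means fallback with per-cluster moments
    km <- with_seed(seed + 1L, stats::kmeans(z0, centers = K, nstart = 5L))
    muK <- km$centers
    varK <- t(vapply(seq_len(K), function(k) {
      zk <- z0[km$cluster == k, , drop = FALSE]
      if (nrow(zk) < 2L) rep(var_floor, d) else apply(zk, 2L, var)
    }, numeric(d)))
  }
  gmm_params(K, muK, log(pmax(varK, var_floor)))
}

#' Dynamic graph-evolution training
#'
#' For each outer iteration: optimize the full objective (reconstruction +
#' adjacency + weighted KL to the MoG prior), assign each spot to its most
#' responsible component at the posterior mean, prune edges crossing
#' components, and continue on the pruned graph. Stops early when a pruning
#' pass removes no edges. With `cfg$fixed_graph` the pruning is skipped.
#'
#' @param dataset A `multislice_dataset`.
#' @param graph The `unified_graph` used for pretraining.
#' @param pre Result of [pretrain()].
#' @param gmm A [gmm_params()] from [init_gmm()].
#' @param cfg A [train_config()].
#' @return A `fit_result`: `z` (evaluation-mode posterior means, n x d),
#'   `assignments` (1-based component per spot), `model`, `graph` (final),
#'   `graph_history` (edge counts per iteration), `loss_history`, `config`.
#' @export
fit_dynamic <- function(dataset, graph, pre, gmm, cfg = train_config()) {
  model <- pre$model
  model$gmm <- gmm
  seeds <- pre$seeds
  Xt <- t(dataset$X)
  Xm <- dataset$X
  slice_index <- dataset$slice_of + 1L
  ps <- trainable_params(model)
  st <- adam_init(ps)   # fresh moments: the parameter set grew
  hist <- pre$loss_history
  ghist <- nrow(graph$edges)
  for (it in seq_len(cfg$outer_its) - 1L) {
    edges <- edge_index(graph)
    A_dense <- as.matrix(graph_adjacency(graph, self_loops = TRUE))
    r <- run_epochs(Xt, Xm, edges, A_dense, slice_index, model, cfg,
                    use_kl = TRUE, n_epochs = cfg$inner_epochs, ps, st,
                    seed = seeds[3L] + 7919L * it, loss_history = hist)
    model <- r$model; ps <- r$ps; st <- r$st; hist <- r$loss_history
    mu_eval <- encode(dataset$X, graph, model$enc, eval_mode = TRUE)$mu
    # refresh the mixture on the current latent: the BN decoder leaves the
    # latent scale free to drift, so the components are re-estimated by EM
    # before each assignment/pruning pass (gradient updates continue to
    # fine-tune them within each cycle)
    model$gmm <- init_gmm(mu_eval, model$gmm$K, seed = seeds[4L] + it)
    ps <- trainable_params(model)
    st$m$gmm.mu[] <- 0; st$v$gmm.mu[] <- 0
    st$m$gmm.logvar[] <- 0; st$v$gmm.logvar[] <- 0
    assignments <- max.col(gmm_responsibilities(mu_eval, model$gmm),
                           ties.method = "first")
    if (cfg$fixed_graph) {
      graph$it <- graph$it + 1L
      ghist <- c(ghist, nrow(graph$edges))
    } else {
      pruned <- prune_graph(graph, assignments)
      removed <- nrow(graph$edges) - nrow(pruned$edges)
      graph <- pruned
      ghist <- c(ghist, nrow(graph$edges))
      if (nrow(graph$edges) == 0L)
        warning("graph became edgeless; continuing with self-loops only",
                call. = FALSE)
      if (removed == 0L) break
    }
  }
  mu_eval <- encode(dataset$X, graph, model$enc, eval_mode = TRUE)$mu
  model$gmm <- init_gmm(mu_eval, model$gmm$K, seed = seeds[4L])
  assignments <- max.col(gmm_responsibilities(mu_eval, model$gmm),
                         ties.method = "first")
  structure(list(z = mu_eval, assignments = assignments, model = model,
                 graph = graph, graph_history = ghist, loss_history = hist,
                 config = cfg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d spots, d=%d, K=%d, edges %s\n", nrow(x$z),
              ncol(x$z), x$model$gmm$K,
              paste(x$graph_history, collapse = " -> ")))
  invisible(x)
}

#' Full integration pipeline: pretrain, initialize mixture, dynamic fit
#'
#' @inheritParams fit_dynamic
#' @param K Number of mixture components; default [estimate_k()] on the
#'   dataset.
#' @return A `fit_result` (see [fit_dynamic()]).
#' @export
integrate_slices <- function(dataset, graph, cfg = train_config(),
                             K = NULL) {
  K <- K %||% estimate_k(dataset$X)
  pre <- pretrain(dataset, graph, cfg)
  gmm <- init_gmm(pre$z0, K, seed = pre$seeds[4L])
  fit_dynamic(dataset, graph, pre, gmm, cfg)
}

#' Cluster a latent embedding
#'
#' @param z n x d latent matrix.
#' @param method `"gmm"` (EM with `K` diagonal components) or `"louvain"`
#'   (community detection on a kNN graph at `resolution`).
#' @param K Components for gmm; must be <= n.
#' @param resolution Louvain resolution.
#' @param knn Neighbours for the louvain kNN graph.
#' @param seed Seed.
#' @return Integer cluster assignment (1-based).
#' @export
cluster_latent <- function(z, method = c("gmm", "louvain"), K = NULL,
                           resolution = 1, knn = 15L, seed = 1L) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("z must be finite", call. = FALSE)
  if (method == "gmm") {
    stopifnot(!is.null(K))
    if (K > nrow(z)) stop("K exceeds the number of spots", call. = FALSE)
    if (K == 1L) return(rep(1L, nrow(z)))
    gmm <- init_gmm(z, K, seed = seed)
    max.col(gmm_responsibilities(z, gmm), ties.method = "first")
  } else {
    k <- min(knn, nrow(z) - 1L)
    nn <- knn_index(z, z, k + 1L)[, -1L, drop = FALSE]
    ed <- undirected_unique(cbind(rep(seq_len(nrow(z)), k), as.vector(nn)))
    g <- igraph::graph_from_edgelist(ed, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(z) - igraph::vcount(g)))
    cl <- with_seed(seed,
      igraph::cluster_louvain(g, resolution = resolution))
    as.integer(igraph::membership(cl))
  }
}

#' Reconstruct (denoise) expression from a trained model
#'
#' Decodes the evaluation-mode posterior means through the slice-specific
#' batch-normalizing decoder.
#'
#' @param fit A `fit_result`.
#' @param dataset The `multislice_dataset` it was trained on.
#' @return Genes x spots matrix, same shape as `dataset$X`.
#' @export
denoise_expression <- function(fit, dataset) {
  out <- decode_expression(fit$z, dataset$slice_of, fit$model$dec)
  dimnames(out) <- dimnames(dataset$X)
  out
}
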
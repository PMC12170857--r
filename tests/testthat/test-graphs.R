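test_that("knn intra edges are symmetric with deterministic tie-breaks", {
  # 2 spots: single edge
  expect_equal(build_intra_edges(rbind(c(0, 0), c(1, 0)), "knn", k = 1L),
               cbind(u = 1L, v = 2L))
  # 4 collinear equally spaced spots, k=1: middle spots tie-break to the
  # lower index, symmetrization yields {(1,2),(2,3),(3,4)}
  coords <- cbind(0:3, 0)
  e <- build_intra_edges(coords, "knn", k = 1L)
  expect_equal(e, cbind(u = c(1L, 2L, 3L), v = c(2L, 3L, 4L)))
  expect_error(build_intra_edges(matrix(1, 5, 2), "knn"), "identical")
})

test_that("calibrated radius yields mean degree in [5,6] on a 30x30 grid", {
  g <- expand.grid(x = 1:30, y = 1:30)
  e <- build_intra_edges(as.matrix(g), mode = "radius")
  deg <- 2 * nrow(e) / 900
  expect_gte(deg, 5); expect_lte(deg, 6)
  # brute force: all strictly closer pairs are edges; only the outermost
  # tied distance ring may be partially included
  D <- as.matrix(dist(g))
  du <- D[upper.tri(D)]
  r_used <- max(D[cbind(e[, 1], e[, 2])])
  expect_gte(nrow(e), sum(du < r_used - 1e-12))
  expect_lte(nrow(e), sum(du <= r_used))
})

test_that("knn mean degree is bounded between k and 2k after symmetrization", {
  set.seed(2)
  for (k in c(3L, 6L)) {
    coords <- matrix(runif(200), 100)
    e <- build_intra_edges(coords, "knn", k = k)
    deg <- 2 * nrow(e) / 100
    expect_gte(deg, k); expect_lte(deg, 2 * k)
  }
})

test_that("MNN edges are mutual and recover planted matched pairs", {
  # two single-spot slices: mutual by necessity
  f <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  e <- build_mnn_edges(f, slice_of = c(0L, 1L), k_mnn = 1L)
  expect_equal(unname(e), cbind(1L, 2L))
  # mutuality violated: u's only neighbour in slice 1 is v, but v's nearest
  # in slice 0 is w != u, so (u, v) must not appear (angles: u=0, w=26,
  # v=18 degrees under the cosine metric)
  f2 <- rbind(c(1, 0), c(cos(0.45), sin(0.45)), c(cos(0.31), sin(0.31)))
  e2 <- build_mnn_edges(f2, slice_of = c(0L, 0L, 1L), k_mnn = 1L)
  expect_equal(unname(e2), cbind(2L, 3L))  # only the mutual pair survives
  # planted matched pairs with small noise
  set.seed(9)
  base <- matrix(rnorm(20 * 5), 20)
  feats <- rbind(base, base + matrix(rnorm(100, 0, 0.01), 20))
  e3 <- build_mnn_edges(feats, slice_of = rep(0:1, each = 20L), k_mnn = 3L)
  planted <- sum(vapply(1:20, function(i)
    any(e3[, 1] == i & e3[, 2] == i + 20L), TRUE))
  expect_gte(planted, 18L)
  # invariance to within-slice spot ordering
  perm <- c(sample(1:20), 20L + sample(1:20))
  e4 <- build_mnn_edges(feats[perm, ], slice_of = rep(0:1, each = 20L),
                        k_mnn = 3L)
  remap <- order(perm)
  e4_orig <- t(apply(e4, 1L, function(r) sort(perm[r])))
  expect_setequal(paste(e4_orig[, 1], e4_orig[, 2]),
                  paste(e3[, 1], e3[, 2]))
})

test_that("unified graph stores a deduplicated union with provenance", {
  intra <- list(cbind(1L, 2L), cbind(1L, 2L))
  slice_of <- c(0L, 0L, 1L, 1L)
  g <- unified_graph(intra, cbind(c(1L, 1L), c(3L, 3L)), slice_of)
  expect_equal(nrow(g$edges), 3L)   # duplicates collapsed
  expect_equal(sum(g$edges$provenance == "inter"), 1L)
  expect_equal(g$it, 0L)
  # no inter edges at all
  g2 <- unified_graph(intra, matrix(integer(0), 0L, 2L), slice_of)
  expect_equal(sum(g2$edges$provenance == "inter"), 0L)
  # random sets: |E| equals the deduplicated union
  set.seed(4)
  n <- 30L; so <- rep(0:1, each = 15L)
  ia <- cbind(sample(15L, 40L, TRUE), sample(15L, 40L, TRUE))
  ib <- cbind(15L + sample(15L, 40L, TRUE), 15L + sample(15L, 40L, TRUE))
  ie <- cbind(sample(15L, 30L, TRUE), 15L + sample(15L, 30L, TRUE))
  g3 <- unified_graph(rbind(ia, ib), ie, so, global = TRUE)
  key <- function(m) unique(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  all_keys <- unique(c(key(ia[ia[, 1] != ia[, 2], , drop = FALSE]),
                       key(ib[ib[, 1] != ib[, 2], , drop = FALSE]),
                       key(ie)))
  expect_equal(nrow(g3$edges), length(all_keys))
  # adjacency is symmetric, zero-diagonal, binary
  A <- graph_adjacency(g3)
  expect_true(Matrix::isSymmetric(A))
  expect_equal(max(abs(Matrix::diag(A))), 0)
  expect_true(all(A@x %in% c(0, 1)))
})

test_that("pruning removes exactly the cross-component edges", {
  set.seed(8)
  n <- 40L
  so <- rep(0:1, each = 20L)
  intra <- cbind(sample(20L, 60L, TRUE), sample(20L, 60L, TRUE))
  inter <- cbind(sample(20L, 30L, TRUE), 20L + sample(20L, 30L, TRUE))
  g <- unified_graph(intra, inter, so, global = TRUE)
  asg <- sample(3L, n, replace = TRUE)
  gp <- prune_graph(g, asg)
  keep_oracle <- asg[g$edges$u] == asg[g$edges$v]
  expect_equal(gp$edges, g$edges[keep_oracle, ],
               ignore_attr = "row.names")
  expect_equal(gp$it, g$it + 1L)
  expect_lte(nrow(gp$edges), nrow(g$edges))
  # all spots one component: unchanged
  expect_equal(prune_graph(g, rep(1L, n))$edges, g$edges)
  # bipartite components: all edges vanish when assignment = side
  gb <- unified_graph(matrix(integer(0), 0L, 2L), inter, so, global = TRUE)
  expect_equal(nrow(prune_graph(gb, so + 1L)$edges), 0L)
  expect_error(prune_graph(g, asg[-1]), "mismatch")
})

test_that("graphs round-trip through the edge-list TSV", {
  setup <- tiny_setup()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(setup$graph, p)
  g2 <- read_graph_tsv(p, setup$ds$slice_of)
  expect_equal(g2$edges, setup$graph$edges)
})
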
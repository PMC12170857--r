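test_that("normalization scales spots to the target sum and preserves zeros", {
  counts <- matrix(c(4, 0, 1, 1, 0, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), NULL))
  s <- raw_slice(counts, coords = matrix(runif(6), 3), slice_id = "a")
  norm <- normalize_log(s, target_sum = 2)
  # hand arithmetic: spot1 (4,0) -> (2,0); spot2 (1,1) -> (1,1); zero spot stays
  expect_equal(norm$counts, log1p(matrix(c(2, 0, 1, 1, 0, 0), nrow = 2,
                                         dimnames = dimnames(counts))))
  expect_true(all(norm$counts >= 0))
  # already at target sum: identity up to log1p
  c2 <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("g1", "g2"), NULL))
  s2 <- raw_slice(c2, coords = matrix(runif(4), 2), slice_id = "b")
  expect_equal(normalize_log(s2, target_sum = 2)$counts, log1p(c2))
  # empty slice errors
  s3 <- raw_slice(matrix(0, 2, 2, dimnames = list(c("g1", "g2"), NULL)),
                  coords = matrix(runif(4), 2), slice_id = "c")
  expect_error(normalize_log(s3), "empty slice")
})

test_that("HVG intersection recovers planted high-dispersion genes", {
  set.seed(3)
  m <- 800L; n <- 150L
  planted <- sort(sample(m, 200L))
  mu_g <- exp(rnorm(m, log(3), 0.6))   # heterogeneous baseline means
  make_slice <- function(id) {
    # planted genes keep their gene's baseline mean but are heavily
    # overdispersed, so mean-binned normalized dispersion must find them
    counts <- matrix(rpois(m * n, mu_g), m)
    counts[planted, ] <- matrix(rnbinom(200L * n, mu = mu_g[planted],
                                        size = 0.25), 200L)
    rownames(counts) <- sprintf("g%04d", seq_len(m))
    normalize_log(raw_slice(counts, coords = matrix(runif(2 * n), n),
                            slice_id = id))
  }
  slices <- lapply(c("a", "b", "c"), make_slice)
  common <- suppressWarnings(select_common_hvgs(slices, n_hvg = 220L))
  hits <- sum(sprintf("g%04d", planted) %in% common)
  expect_gte(hits, 190L)
  # invariance to slice order
  expect_identical(common,
                   suppressWarnings(select_common_hvgs(rev(slices), 220L)))
  # invariance to gene-row permutation
  perm <- slices
  o <- sample(m)
  perm[[2]]$counts <- perm[[2]]$counts[o, ]
  perm[[2]]$gene_ids <- perm[[2]]$gene_ids[o]
  expect_identical(common, suppressWarnings(select_common_hvgs(perm, 220L)))
})

test_that("assembly concatenates slices and is gene-order invariant", {
  mk <- function(id, genes, n = 2L) {
    counts <- matrix(seq_len(length(genes) * n), length(genes),
                     dimnames = list(genes, NULL))
    raw_slice(counts, coords = matrix(runif(2 * n), n), slice_id = id)
  }
  s1 <- mk("a", c("g1", "g2", "g3"))
  s2 <- mk("b", c("g1", "g2", "g3"))
  ds <- assemble_dataset(list(s1, s2), c("g1", "g3"))
  expect_equal(dim(ds$X), c(2L, 4L))
  expect_equal(ds$slice_of, c(0L, 0L, 1L, 1L))
  expect_equal(rownames(ds$X), c("g1", "g3"))
  # shuffled gene order in slice 2 gives the same X
  s2b <- s2; o <- c(3L, 1L, 2L)
  s2b$counts <- s2b$counts[o, ]; s2b$gene_ids <- s2b$gene_ids[o]
  expect_equal(assemble_dataset(list(s1, s2b), c("g1", "g3"))$X, ds$X)
  # single slice restricted to common genes
  expect_equal(assemble_dataset(list(s1), c("g1", "g3"))$X,
               s1$counts[c("g1", "g3"), ])
  expect_error(assemble_dataset(list(s1, mk("c", c("g1", "g2"))),
                                c("g1", "g3")), "missing gene 'g3'")
})

test_that("K estimation counts signal eigenvalues above the noise bulk", {
  set.seed(11)
  # exact low-rank: 3 factors, no noise
  U <- matrix(rnorm(120 * 3), 120); V <- matrix(rnorm(3 * 200), 3)
  X0 <- U %*% V
  expect_equal(estimate_k(X0, k_min = 1L), 3L)
  # rank-5 signal buried in iid noise, signal well above the bulk edge
  U5 <- matrix(rnorm(300 * 5), 300); V5 <- matrix(rnorm(5 * 400), 5)
  X5 <- 6 * U5 %*% V5 + matrix(rnorm(300 * 400), 300)
  expect_equal(estimate_k(X5), 5L)
  # column permutation invariance
  expect_equal(estimate_k(X5[, sample(400)]), 5L)
  # degenerate constant matrix errors
  expect_error(estimate_k(matrix(1, 10, 10)), "degenerate")
})

test_that("slice containers validate their invariants", {
  expect_error(raw_slice(matrix(1, 2, 2), c("g1", "g1"),
                         matrix(0, 2, 2), "a"), "unique")
  expect_error(raw_slice(matrix(1, 2, 3), c("g1", "g2"),
                         matrix(0, 2, 2), "a"), "coords")
  expect_error(raw_slice(matrix(-1, 2, 2), c("g1", "g2"),
                         matrix(0, 2, 2), "a"), "non-negative")
  expect_error(raw_slice(matrix(1, 2, 2), c("g1", "g2"), matrix(0, 2, 2),
                         "a", clinical = list(time = -1, event = 1)),
               "survival_time")
})
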
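#' @useDynLib spniche, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rexp runif rbeta rnbinom var prcomp dist median
#'   cmdscale setNames quantile
#' @importFrom utils read.table write.table modifyList
NULL

# Derive a stream of child seeds from one master seed, so that independent
# stages (init, sampling, GMM, UMAP, folds) do not share RNG state.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a local RNG seed, restoring caller state afterwards.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise softmax of a matrix
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
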
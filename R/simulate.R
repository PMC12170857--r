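#' Configuration for the synthetic multi-slice generator
#'
#' Defines the generative conditions for a multi-slice spatial dataset with
#' planted spatial domains, slice-specific batch effects, and slice-level
#' clinical labels driven by domain composition.
#'
#' @param L Number of slices.
#' @param n_spots Spots per slice.
#' @param m Number of genes.
#' @param K_true Number of planted spatial domains.
#' @param layout Spatial layout of domains: `"strips"` lays domains out as
#'   horizontal bands (cortical-layer-like), `"blobs"` as Gaussian islands
#'   (tumor-region-like).
#' @param domain_effect Log-scale mean shift applied to a domain's exclusive
#'   marker-gene block in spots of that domain.
#' @param markers_per_domain Number of exclusive marker genes per domain.
#' @param batch_scale Standard deviation of the per-slice, per-gene log-mean
#'   shift emulating batch effects.
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param composition_alpha Dirichlet concentration for per-slice domain
#'   composition (smaller = more variable compositions across slices).
#'   Either a scalar, a length-`K_true` vector, or an `L x K_true` matrix
#'   of per-slice concentrations for designed cohorts (e.g. a case/control
#'   split on one domain's abundance).
#' @param seed Master seed; every random draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(L = 3L, n_spots = 300L, m = 600L, K_true = 4L,
                       layout = c("strips", "blobs"),
                       domain_effect = 1.0, markers_per_domain = 50L,
                       batch_scale = 0.3, dispersion = 0.3,
                       composition_alpha = 3, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(L >= 1, n_spots >= 4, m >= K_true * markers_per_domain,
            K_true >= 2, domain_effect >= 0, batch_scale >= 0,
            dispersion >= 0)
  structure(list(L = as.integer(L), n_spots = as.integer(n_spots),
                 m = as.integer(m), K_true = as.integer(K_true),
                 layout = layout, domain_effect = domain_effect,
                 markers_per_domain = as.integer(markers_per_domain),
                 batch_scale = batch_scale, dispersion = dispersion,
                 composition_alpha = composition_alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) stats::rgamma(1L, shape = a, rate = 1), 0)
  g / sum(g)
}

# Domain label per spot given a layout and a target composition vector.
layout_domains <- function(coords, comp, layout, K) {
  n <- nrow(coords)
  if (layout == "strips") {
    edges <- cumsum(comp)
    lab <- findInterval(coords[, 2L], c(-Inf, edges[-K]))
    as.integer(pmin(lab, K))
  } else {
    # blob centers on a jittered circle; nearest-center assignment with
    # per-domain radii scaled so larger compositions claim more area
    ang <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)] + runif(1L, 0, 2 * pi)
    centers <- cbind(0.5 + 0.33 * cos(ang), 0.5 + 0.33 * sin(ang))
    d2 <- outer(coords[, 1L], centers[, 1L], "-")^2 +
      outer(coords[, 2L], centers[, 2L], "-")^2
    scaled <- sweep(d2, 2L, pmax(comp, 1e-3)^2, "/")
    as.integer(apply(scaled, 1L, which.min))
  }
}

#' Simulate a multi-slice spatial dataset with planted domains
#'
#' Generates `L` slices sharing `K_true` spatial domains. Each domain owns an
#' exclusive block of marker genes whose log-mean is raised by
#' `domain_effect` in spots of that domain; each slice receives an
#' independent gene-wise log-mean shift of scale `batch_scale` (batch
#' effect). Counts are negative binomial. Fully determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `slices` (list of `raw_slice` objects, see
#'   [raw_slice()]) and `truth` (`sim_truth`: per-spot domain labels,
#'   per-slice composition, marker-block map, and generator parameters).
#' @export
simulate_slices <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 2L + cfg$L)
  K <- cfg$K_true; m <- cfg$m
  gene_ids <- sprintf("gene%04d", seq_len(m))
  marker_block <- rep(0L, m)
  marker_block[seq_len(K * cfg$markers_per_domain)] <-
    rep(seq_len(K), each = cfg$markers_per_domain)
  base_logmu <- with_seed(seeds[1L], rnorm(m, mean = 0, sd = 1))
  batch_shift <- with_seed(seeds[2L],
    matrix(rnorm(m * cfg$L, 0, cfg$batch_scale), nrow = m, ncol = cfg$L))

  slices <- vector("list", cfg$L)
  domains <- vector("list", cfg$L)
  comp <- matrix(0, cfg$L, K)
  for (i in seq_len(cfg$L)) {
    slices_i <- with_seed(seeds[2L + i], {
      side <- ceiling(sqrt(cfg$n_spots))
      g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(cfg$n_spots), ]
      coords <- (as.matrix(g) - 0.5) / side +
        matrix(runif(2L * cfg$n_spots, -0.15 / side, 0.15 / side),
               ncol = 2L)
      ca <- cfg$composition_alpha
      alpha_i <- if (is.matrix(ca)) ca[i, ]
        else if (length(ca) == K) ca else rep(ca, K)
      ci <- rdirichlet1(alpha_i)
      dom <- layout_domains(coords, ci, cfg$layout, K)
      logmu <- matrix(base_logmu + batch_shift[, i], m, cfg$n_spots)
      for (k in seq_len(K)) {
        sel <- dom == k
        if (any(sel)) logmu[marker_block == k, sel] <-
            logmu[marker_block == k, sel] + cfg$domain_effect
      }
      mu <- exp(logmu)
      counts <- if (cfg$dispersion > 0) {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
               m, cfg$n_spots)
      } else {
        matrix(stats::rpois(length(mu), lambda = mu), m, cfg$n_spots)
      }
      dimnames(counts) <- list(gene_ids,
                               sprintf("s%d_spot%04d", i, seq_len(cfg$n_spots)))
      list(slice = raw_slice(counts, gene_ids, coords,
                             slice_id = sprintf("slice%d", i)),
           dom = dom)
    })
    slices[[i]] <- slices_i$slice
    domains[[i]] <- slices_i$dom
    comp[i, ] <- tabulate(slices_i$dom, K) / cfg$n_spots
  }
  truth <- structure(list(domains = domains, composition = comp,
                          marker_block = marker_block,
                          base_logmu = base_logmu,
                          batch_shift = batch_shift, config = cfg),
                     class = "sim_truth")
  list(slices = slices, truth = truth)
}

#' Attach exponential survival outcomes driven by domain composition
#'
#' Per-slice hazard is `exp(beta_sim * composition[target_domain])`; event
#' times are exponential with that rate, and an independent exponential
#' censoring time is calibrated so each slice is censored with probability
#' `censoring`.
#'
#' @param truth A `sim_truth` from [simulate_slices()].
#' @param beta_sim Log-hazard coefficient on the target domain's proportion.
#' @param censoring Target censoring fraction in `[0, 1)`.
#' @param target_domain Index of the hazard-driving domain.
#' @param seed Seed (defaults to a child of the generator's master seed).
#' @return A data.frame with `slice_id`, `time`, `event` (1 = observed).
#' @export
attach_survival <- function(truth, beta_sim = 3, censoring = 0.3,
                            target_domain = 1L, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), censoring >= 0, censoring < 1)
  seed <- seed %||% derive_seeds(truth$config$seed, 4L)[3L]
  hazard <- exp(beta_sim * truth$composition[, target_domain])
  with_seed(seed, {
    t_event <- rexp(length(hazard), rate = hazard)
    t_cens <- if (censoring > 0)
      rexp(length(hazard), rate = hazard * censoring / (1 - censoring))
    else rep(Inf, length(hazard))
    data.frame(slice_id = sprintf("slice%d", seq_along(hazard)),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}

#' Attach binary class labels from domain composition
#'
#' Class 1 if the target domain's proportion exceeds `threshold` (default:
#' the median proportion across slices), emulating e.g. metastasis-enriched
#' niches.
#'
#' @inheritParams attach_survival
#' @param threshold Composition cutoff; default median across slices.
#' @return data.frame with `slice_id`, `class` (factor with levels 0/1).
#' @export
attach_classes <- function(truth, target_domain = 1L, threshold = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- truth$composition[, target_domain]
  threshold <- threshold %||% median(p)
  cls <- as.integer(p > threshold)
  if (length(unique(cls)) < 2L)
    stop("degenerate single-class outcome: adjust threshold", call. = FALSE)
  data.frame(slice_id = sprintf("slice%d", seq_along(p)),
             class = factor(cls, levels = c(0L, 1L)))
}
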
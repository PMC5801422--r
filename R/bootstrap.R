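# Parametric residual bootstrap.  Replicate b regenerates, for every gene,
# probe-level log2 intensities as
#   fitted signal (overall + probe effect + array effect)  +  N(0, sigma2)
# with sigma2 the gene's two-way MSE, so the mean signal over replicates
# retains the original expression (the bootstrap is centered at the observed
# signal).  Each (replicate, gene) pair draws from its own derived RNG
# substream, making ensembles reproducible regardless of iteration order.

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer root seed; every source of randomness in an ensemble
#'   derives from it.
#' @return an object of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(B = 100L, seed = 1L) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  structure(list(B = B, seed = as.integer(seed), noise_model = "gaussian"),
    class = "bootstrap_config"
  )
}

# Derived substream key for (seed, replicate, gene); unique per (b, g) for
# g < 1e6 and kept inside the 32-bit integer range set.seed() accepts.
.derive_seed <- function(seed, b, g) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(b) + as.numeric(g)) %%
    2147483647)
}

#' Generate one parametric bootstrap replicate
#'
#' Log2 intensity at (g, p, t) is
#' `overall_g + probe_effect_g[p] + array_effect_g[t] + e`, with `e` drawn
#' iid `N(0, sigma2_g)`. Deterministic given `(seed, replicate_index)`.
#'
#' @param fits a `"gene_fit_collection"` with `sigma2` set for every gene.
#' @param replicate_index which replicate `b` (1-based).
#' @param seed integer root seed.
#' @return a `"probe_dataset"` on the log2 scale.
#' @export
generate_replicate <- function(fits, replicate_index, seed) {
  stopifnot(inherits(fits, "gene_fit_collection"))
  G <- length(fits$fits)
  P <- length(fits$fits[[1L]]$probe_effects)
  T_ <- length(fits$fits[[1L]]$array_effects)
  arr <- array(NA_real_, dim = c(G, P, T_))
  for (g in seq_len(G)) {
    f <- fits$fits[[g]]
    if (is.null(f$sigma2) || is.na(f$sigma2)) {
      stop("fit has no sigma2; run fit_all_genes on data with P >= 2")
    }
    mu <- f$overall + outer(f$probe_effects, f$array_effects, "+")
    set.seed(.derive_seed(seed, replicate_index, g))
    arr[g, , ] <- mu + rnorm(P * T_, mean = 0, sd = sqrt(f$sigma2))
  }
  probe_dataset(arr, fits$gene_ids, fits$time_points, is_log_scale = TRUE)
}

#' Generate a bootstrap ensemble
#'
#' Replicate `b` equals `generate_replicate(fits, b, config$seed)`. With
#' `materialize = FALSE` a generator function is returned instead of a list,
#' keeping memory at one replicate.
#'
#' @param fits a `"gene_fit_collection"`.
#' @param config a `"bootstrap_config"`.
#' @param materialize return a list of datasets (`TRUE`) or a
#'   `function(b)` generator (`FALSE`).
#' @return list of `config$B` probe datasets, or a generator function.
#' @export
generate_ensemble <- function(fits, config, materialize = TRUE) {
  stopifnot(inherits(config, "bootstrap_config"))
  gen <- function(b) generate_replicate(fits, b, config$seed)
  if (!materialize) {
    return(gen)
  }
  lapply(seq_len(config$B), gen)
}

#' Variance-stabilizing transform for count matrices
#'
#' Entry point for RNA-seq style counts: Poisson counts are stabilized with
#' `2 * sqrt(x)`; negative-binomial counts (variance `mu + mu^2 / dispersion`)
#' with `asinh(sqrt(x / dispersion))`. The transformed matrix is suitable as
#' log-scale-like input to [fit_all_genes()].
#'
#' @param counts nonnegative numeric matrix (gene x time).
#' @param model `"poisson"` or `"negative_binomial"`.
#' @param dispersion positive size parameter, required for
#'   `"negative_binomial"`.
#' @return numeric matrix of the same shape.
#' @export
variance_stabilize_counts <- function(counts,
                                      model = c("poisson", "negative_binomial"),
                                      dispersion = NULL) {
  model <- match.arg(model)
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (model == "poisson") {
    if (!is.null(dispersion)) stop("dispersion is only used for negative_binomial")
    return(2 * sqrt(counts))
  }
  if (is.null(dispersion) || !is.finite(dispersion) || dispersion <= 0) {
    stop("negative_binomial requires a positive dispersion")
  }
  asinh(sqrt(counts / dispersion))
}
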
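# Synthetic probe-level time-course data with known ground truth.  Each
# gene's log2 intensities follow the same additive two-way structure the
# bootstrap model assumes -- median-centered probe affinities plus a
# per-array (temporal) effect plus iid Gaussian noise -- with the rhythmic
# signal carried in the array effects.  A separate step injects array-level
# technical distortions (the variation normalization is meant to remove)
# without touching the ground truth.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate a dense long-series circadian design: 300 genes with 8
#' probes each over 48 equispaced time points spanning two 24-index
#' periods, 30% rhythmic genes with log2 amplitudes 0.5-2 over baselines of
#' 6-12 log2 units, probe affinity spread 1 log2 unit and per-gene noise SD
#' 0.2-0.6 log2 units.
#'
#' @param G,P,T dimensions: genes, probes per gene, time points.
#' @param fraction_rhythmic fraction of genes carrying a rhythmic signal.
#' @param period oscillation period in time-index units (default `T / 2`,
#'   two full cycles across the design).
#' @param amplitude_range log2 amplitude interval for rhythmic genes.
#' @param baseline_range log2 baseline expression interval.
#' @param probe_effect_sd SD of the Gaussian probe affinities (log2 units).
#' @param noise_sd_range per-gene noise SD interval (log2 units); use
#'   `c(0, 0)` for exact, noise-free data.
#' @param bias_model array-level technical bias: `"none"`, `"offset"`,
#'   `"scale"` or `"nonlinear"` (applied by [inject_array_bias()]).
#' @param bias_magnitude nonnegative bias strength.
#' @param waveform `"cosine"` or `"asymmetric"` (cosine cubed: sharper,
#'   asymmetric-looking peaks).
#' @param seed integer seed; generation is deterministic given the config.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(G = 300L, P = 8L, T = 48L,
                             fraction_rhythmic = 0.3,
                             period = T / 2,
                             amplitude_range = c(0.5, 2.0),
                             baseline_range = c(6, 12),
                             probe_effect_sd = 1.0,
                             noise_sd_range = c(0.2, 0.6),
                             bias_model = c("none", "offset", "scale", "nonlinear"),
                             bias_magnitude = 0,
                             waveform = c("cosine", "asymmetric"),
                             seed = 17L) {
  bias_model <- match.arg(bias_model)
  waveform <- match.arg(waveform)
  cfg <- list(
    G = as.integer(G), P = as.integer(P), T = as.integer(T),
    fraction_rhythmic = fraction_rhythmic, period = period,
    amplitude_range = amplitude_range, baseline_range = baseline_range,
    probe_effect_sd = probe_effect_sd, noise_sd_range = noise_sd_range,
    bias_model = bias_model, bias_magnitude = bias_magnitude,
    waveform = waveform, seed = as.integer(seed)
  )
  if (cfg$G < 1L || cfg$P < 1L || cfg$T < 2L) stop("invalid dimensions")
  if (fraction_rhythmic < 0 || fraction_rhythmic > 1) {
    stop("fraction_rhythmic must be in [0, 1]")
  }
  for (rng in list(amplitude_range, baseline_range, noise_sd_range)) {
    if (length(rng) != 2L || rng[2L] < rng[1L]) stop("range must be well-ordered")
  }
  if (any(noise_sd_range < 0) || probe_effect_sd < 0 || bias_magnitude < 0) {
    stop("spreads must be nonnegative")
  }
  if (period <= 0 || period > cfg$T) stop("period must be in (0, T]")
  structure(cfg, class = "synthetic_config")
}

.waveform_signal <- function(tt, amplitude, phase, period, waveform) {
  u <- cos(2 * pi * (tt - phase) / period)
  if (waveform == "asymmetric") u <- u^3
  amplitude * u
}

#' Generate a synthetic probe-level dataset with ground truth
#'
#' Per gene: baseline ~ U(baseline_range); probe effects ~ N(0,
#' probe_effect_sd^2), median-centered; array effect
#' `beta_t = baseline + A * cos(2 pi (t - phase) / period)` for rhythmic
#' genes (amplitude A = 0 for flat genes); log2 intensity =
#' `probe_effect + beta_t + N(0, sigma_g^2)`. If the config requests an
#' array bias model, it is injected afterwards via [inject_array_bias()].
#'
#' @param config a `"synthetic_config"`.
#' @return list with `dataset` (a log2-scale `"probe_dataset"`) and `truth`
#'   (data.frame: `gene_id`, `is_rhythmic`, `amplitude`, `phase`,
#'   `noise_sd`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  G <- config$G; P <- config$P; T_ <- config$T
  tt <- seq_len(T_) - 1
  gene_ids <- sprintf("gene_%04d", seq_len(G))

  n_rhythmic <- round(G * config$fraction_rhythmic)
  is_rhythmic <- rep(FALSE, G)
  is_rhythmic[sample.int(G, n_rhythmic)] <- TRUE
  amplitude <- ifelse(
    is_rhythmic,
    runif(G, config$amplitude_range[1L], config$amplitude_range[2L]), 0
  )
  phase <- runif(G, 0, config$period)
  baseline <- runif(G, config$baseline_range[1L], config$baseline_range[2L])
  noise_sd <- runif(G, config$noise_sd_range[1L], config$noise_sd_range[2L])

  arr <- array(NA_real_, dim = c(G, P, T_))
  for (g in seq_len(G)) {
    pe <- rnorm(P, 0, config$probe_effect_sd)
    pe <- pe - median(pe)
    beta <- baseline[g] +
      .waveform_signal(tt, amplitude[g], phase[g], config$period, config$waveform)
    noise <- if (noise_sd[g] > 0) rnorm(P * T_, 0, noise_sd[g]) else 0
    arr[g, , ] <- outer(pe, beta, "+") + noise
  }
  dataset <- probe_dataset(arr, gene_ids, tt, is_log_scale = TRUE)
  if (config$bias_model != "none" && config$bias_magnitude > 0) {
    dataset <- inject_array_bias(
      dataset, config$bias_model, config$bias_magnitude,
      seed = config$seed + 1L
    )
  }
  truth <- data.frame(
    gene_id = gene_ids, is_rhythmic = is_rhythmic,
    amplitude = amplitude, phase = phase, noise_sd = noise_sd,
    stringsAsFactors = FALSE
  )
  list(dataset = dataset, truth = truth)
}

#' Inject array-level technical bias
#'
#' Creates the between-array technical variation normalization is supposed
#' to remove; the biological ground truth is untouched.
#'
#' * `"offset"`: per-array constant log2 shift ~ N(0, bias_magnitude^2).
#' * `"scale"`: per-array multiplicative factor `2^N(0, bias_magnitude^2)`
#'   on the natural intensity scale (equivalently a per-array additive
#'   shift on the log2 scale).
#' * `"nonlinear"`: per-array smooth monotone cubic warp of the log2
#'   intensity axis. The curvature drifts smoothly across arrays (an AR(1)
#'   sequence with lag-1 correlation 0.9, scaled by
#'   `b = min(bias_magnitude, 0.45)` and clamped to keep the warp
#'   monotone), emulating scanner/hybridization drift over the course of
#'   the experiment -- the kind of technical variation that can manufacture
#'   spurious rhythmicity when normalization fails to remove it.
#'
#' @param dataset a `"probe_dataset"` on the log2 scale.
#' @param bias_model `"offset"`, `"scale"` or `"nonlinear"`.
#' @param bias_magnitude nonnegative strength; 0 returns the input
#'   unchanged.
#' @param seed integer seed (deterministic distortion).
#' @return a biased `"probe_dataset"`.
#' @export
inject_array_bias <- function(dataset, bias_model, bias_magnitude, seed = 1L) {
  validate_probe_dataset(dataset)
  if (!dataset$is_log_scale) stop("dataset must be on the log2 scale")
  bias_model <- match.arg(bias_model, c("offset", "scale", "nonlinear"))
  if (bias_magnitude < 0) stop("bias_magnitude must be nonnegative")
  if (bias_magnitude == 0) {
    return(dataset)
  }
  d <- pld_dim(dataset)
  T_ <- d[3L]
  m <- matrix(dataset$intensities, d[1L] * d[2L], T_)
  set.seed(as.integer(seed))
  if (bias_model == "offset") {
    shift <- rnorm(T_, 0, bias_magnitude)
    m <- sweep(m, 2L, shift, "+")
  } else if (bias_model == "scale") {
    fac <- 2^rnorm(T_, 0, bias_magnitude)
    m <- log2(sweep(2^m, 2L, fac, "*"))
  } else {
    b <- min(bias_magnitude, 0.45)
    phi <- 0.9
    z <- numeric(T_)
    z[1L] <- rnorm(1L)
    for (t in seq_len(T_)[-1L]) {
      z[t] <- phi * z[t - 1L] + rnorm(1L, 0, sqrt(1 - phi^2))
    }
    curv <- pmax(pmin(b * z, 0.45), -0.45)
    lo <- min(m); hi <- max(m); rg <- hi - lo
    for (j in seq_len(T_)) {
      u <- (m[, j] - lo) / rg
      w <- (1 - curv[j]) * u + curv[j] * u^3
      m[, j] <- lo + rg * w
    }
  }
  probe_dataset(
    array(m, dim = d), dataset$gene_ids, dataset$time_points,
    is_log_scale = TRUE
  )
}

#' Noise-free dataset paired with its exact two-way decomposition
#'
#' For configs with `noise_sd_range = c(0, 0)` the generated intensities
#' are exactly additive, so each gene's median polish fit is known in
#' closed form: `overall = median(beta)`, probe effects are the planted
#' (median-centered) affinities, array effects are `beta - median(beta)`,
#' residuals and `sigma2` are 0. Useful as an exact test fixture.
#'
#' @param config a `"synthetic_config"` with zero noise.
#' @return list with `dataset` and `fits` (a `"gene_fit_collection"` of the
#'   exact decompositions).
#' @export
median_polish_roundtrip_fixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(config$noise_sd_range != 0)) {
    stop("fixture is exact-only: config must have noise_sd_range = c(0, 0)")
  }
  if (config$bias_model != "none" && config$bias_magnitude > 0) {
    stop("fixture requires bias_model 'none'")
  }
  gen <- generate_dataset(config)
  dataset <- gen$dataset
  G <- config$G
  fits <- vector("list", G)
  for (g in seq_len(G)) {
    m <- gene_matrix(dataset, g)
    # exact additive structure: row p is pe[p] + beta, so any column minus
    # its median recovers pe, and any probe's series minus pe recovers beta
    pe <- m[, 1L] - median(m[, 1L])
    beta <- m[1L, ] - pe[1L]
    fits[[g]] <- structure(
      list(
        overall = median(beta),
        probe_effects = pe,
        array_effects = beta - median(beta),
        residuals = matrix(0, config$P, config$T),
        sigma2 = if (config$P >= 2L) 0 else NA_real_,
        converged = TRUE,
        n_iterations = 1L
      ),
      class = "two_way_fit"
    )
  }
  list(
    dataset = dataset,
    fits = structure(
      list(
        fits = fits, gene_ids = dataset$gene_ids,
        time_points = dataset$time_points
      ),
      class = "gene_fit_collection"
    )
  )
}
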
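# The standard and bootstrap-robust rhythmicity measures, and the pipeline
# orchestration that ties fitting, bootstrapping, normalization,
# summarization and detection together for one (normalization, detector)
# pair.
#
# Standard measure:  M^g = 1 - BH-adjusted p-value^g, in [0, 1].
# Robust measure:    M_Robust^g = E-hat^g - RMSE-hat^g, where over B
#                    bootstrap replicates E-hat is the mean of the
#                    replicate measures and RMSE-hat is the root mean
#                    square deviation of the replicate measures around the
#                    ORIGINAL-data measure (divisor B - 1).  M_Robust can
#                    be negative when replicate-to-replicate variation
#                    exceeds the mean measure.

#' Standard rhythmicity measure M
#'
#' `M^g = 1 - adjusted_pvalue^g`. Values near 1 indicate likely rhythmic
#' genes, near 0 likely non-rhythmic genes.
#'
#' @param result a `"detector_result"` (BH-adjusted p-values present).
#' @param normalization_name name of the normalization the expression matrix
#'   came through (bookkeeping for cross-method comparisons).
#' @return an object of class `"rhythmicity_scores"`: `M`, `gene_ids`,
#'   `normalization`, `detector`.
#' @export
standard_measure <- function(result, normalization_name) {
  stopifnot(inherits(result, "detector_result"))
  structure(
    list(
      M = 1 - result$adjusted_pvalues,
      gene_ids = result$gene_ids,
      normalization = normalization_name,
      detector = result$detector$name
    ),
    class = "rhythmicity_scores"
  )
}

#' @export
print.rhythmicity_scores <- function(x, ...) {
  cat(sprintf(
    "rhythmicity_scores: %d genes, normalization '%s', detector '%s'\n",
    length(x$M), x$normalization, x$detector
  ))
  invisible(x)
}

#' Bootstrap-robust rhythmicity measure
#'
#' Combines the original-data measure with B replicate measures:
#' `E_hat = mean_b(theta_b)`,
#' `RMSE_hat = sqrt(sum_b (theta_b - theta)^2 / (B - 1))` with `theta` the
#' original-data measure (not the bootstrap mean), and
#' `M_robust = E_hat - RMSE_hat`. `M_robust` is not clipped: negative
#' values indicate measures whose sampling variability exceeds their
#' expected value.
#'
#' @param theta_hat a `"rhythmicity_scores"` from the original data.
#' @param bootstrap_scores list of `B >= 2` `"rhythmicity_scores"`, one per
#'   replicate, same genes and same (normalization, detector).
#' @return an object of class `"robust_scores"`: `E_hat`, `RMSE_hat`,
#'   `M_robust`, `B`, `gene_ids`, `normalization`, `detector`.
#' @export
robust_measure <- function(theta_hat, bootstrap_scores) {
  stopifnot(inherits(theta_hat, "rhythmicity_scores"))
  B <- length(bootstrap_scores)
  if (B < 2L) stop("need B >= 2 bootstrap replicates (degrees of freedom)")
  for (s in bootstrap_scores) {
    stopifnot(inherits(s, "rhythmicity_scores"))
    if (!identical(s$gene_ids, theta_hat$gene_ids)) {
      stop("bootstrap scores not aligned on the same genes")
    }
    if (!identical(s$normalization, theta_hat$normalization) ||
      !identical(s$detector, theta_hat$detector)) {
      stop("bootstrap scores from a different (normalization, detector) pair")
    }
  }
  mat <- vapply(bootstrap_scores, function(s) s$M, numeric(length(theta_hat$M)))
  mat <- matrix(mat, nrow = length(theta_hat$M))
  E_hat <- rowMeans(mat)
  RMSE_hat <- sqrt(rowSums((mat - theta_hat$M)^2) / (B - 1))
  structure(
    list(
      E_hat = E_hat,
      RMSE_hat = RMSE_hat,
      M_robust = E_hat - RMSE_hat,
      B = B,
      gene_ids = theta_hat$gene_ids,
      normalization = theta_hat$normalization,
      detector = theta_hat$detector
    ),
    class = "robust_scores"
  )
}

#' @export
print.robust_scores <- function(x, ...) {
  cat(sprintf(
    "robust_scores: %d genes, B = %d, normalization '%s', detector '%s'\n",
    length(x$M_robust), x$B, x$normalization, x$detector
  ))
  invisible(x)
}

#' Full scoring pipeline for one (normalization, detector) pair
#'
#' Fits the per-gene two-way model on the corrected, *unnormalized* log2
#' intensities, scores the original data through
#' normalization -> summarization -> detection -> M, then regenerates each
#' bootstrap replicate from the fits and pushes it through the identical
#' pipeline, finally combining everything into the robust measure. Because
#' replicate b is a deterministic function of `(config$seed, b)`, calling
#' this once per normalization method reuses the same bootstrap replicates
#' across methods, so cross-method differences reflect normalization, not
#' Monte Carlo noise.
#'
#' @param corrected a `"probe_dataset"` (background-corrected, unnormalized,
#'   log2 scale).
#' @param n a `"normalization_method"` or method name.
#' @param a a `"detector_method"`.
#' @param config a `"bootstrap_config"`.
#' @param fits optional precomputed `"gene_fit_collection"` for `corrected`
#'   (saves refitting when scoring several normalizations).
#' @return list with elements `standard` (`"rhythmicity_scores"`), `robust`
#'   (`"robust_scores"`) and `fits`.
#' @export
score_pipeline <- function(corrected, n, a, config, fits = NULL) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (is.character(n)) n <- normalization_method(n)
  if (is.null(fits)) fits <- fit_all_genes(corrected)
  stopifnot(inherits(fits, "gene_fit_collection"))

  score_one <- function(dataset, stage) {
    tryCatch(
      {
        norm <- normalize_dataset(dataset, n)
        expr <- summarize_expression(norm)
        res <- run_detector(expr, a)
        standard_measure(res, n$name)
      },
      error = function(e) {
        stop(sprintf("[%s] %s", stage, conditionMessage(e)))
      }
    )
  }

  theta <- score_one(corrected, "original")
  boot <- vector("list", config$B)
  for (b in seq_len(config$B)) {
    rep_b <- generate_replicate(fits, b, config$seed)
    boot[[b]] <- score_one(rep_b, sprintf("bootstrap replicate %d", b))
  }
  list(standard = theta, robust = robust_measure(theta, boot), fits = fits)
}

#' Write per-gene scores of one (normalization, detector) pair
#'
#' TSV with columns `gene_id`, `M`, `E_hat`, `RMSE_hat`, `M_robust`.
#'
#' @param standard a `"rhythmicity_scores"`.
#' @param robust the matching `"robust_scores"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(standard, robust, path) {
  stopifnot(inherits(standard, "rhythmicity_scores"))
  stopifnot(inherits(robust, "robust_scores"))
  if (!identical(standard$gene_ids, robust$gene_ids)) {
    stop("standard and robust scores not aligned")
  }
  out <- data.frame(
    gene_id = standard$gene_ids,
    M = standard$M,
    E_hat = robust$E_hat,
    RMSE_hat = robust$RMSE_hat,
    M_robust = robust$M_robust,
    stringsAsFactors = FALSE
  )
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read a scores TSV written by [write_scores()]
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `M`, `E_hat`, `RMSE_hat`,
#'   `M_robust`.
#' @export
read_scores <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("gene_id", "M", "E_hat", "RMSE_hat", "M_robust")
  if (!identical(names(d), need)) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  d
}
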
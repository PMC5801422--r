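# Per-gene two-way median polish of log2 intensities.  The decomposition
#   log2(x[p, t]) = overall + probe_effect[p] + array_effect[t] + residual[p, t]
# is the model behind both RMA-style summarization (expression at time t =
# overall + array_effect[t]) and the parametric bootstrap (fitted signal +
# Gaussian noise with variance sigma2 = MSE of the fit).

#' Two-way median polish of a probe x array matrix
#'
#' Alternates row (probe) then column (array) median sweeps until the sum of
#' absolute residuals decreases by less than `tol` times the initial sum, or
#' `max_iter` sweeps are reached. Effects are median-centered, with the
#' centering constants folded into the `overall` term, so the reconstruction
#' `overall + probe_effects[p] + array_effects[t] + residuals[p, t]` equals
#' the input exactly.
#'
#' Medians use the usual midpoint convention for even lengths. `sigma2` is
#' the two-way ANOVA mean squared error, sum of squared residuals over
#' `(P - 1) * (T - 1)`; it is `NA` when `P = 1` (no residual degrees of
#' freedom).
#'
#' @param m numeric `P x T` matrix of log2 intensities (`P >= 1`, `T >= 2`).
#' @param max_iter maximum number of full row+column sweeps.
#' @param tol relative tolerance on the reduction of the sum of absolute
#'   residuals.
#' @return An object of class `"two_way_fit"`: `overall`, `probe_effects`
#'   (length `P`, median 0), `array_effects` (length `T`, median 0),
#'   `residuals` (`P x T`), `sigma2`, `converged`, `n_iterations`.
#' @export
fit_median_polish <- function(m, max_iter = 10L, tol = 1e-4) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop("input matrix must be finite numeric")
  }
  if (nrow(m) < 1L || ncol(m) < 2L) stop("need P >= 1 probes and T >= 2 arrays")
  res <- median_polish_cpp(m, as.integer(max_iter), as.numeric(tol))
  fit <- structure(
    list(
      overall = res$overall,
      probe_effects = res$row_effects,
      array_effects = res$col_effects,
      residuals = res$residuals,
      sigma2 = NA_real_,
      converged = res$converged,
      n_iterations = res$n_iterations
    ),
    class = "two_way_fit"
  )
  if (nrow(m) >= 2L) fit$sigma2 <- compute_mse(fit)
  fit
}

#' @export
print.two_way_fit <- function(x, ...) {
  cat(sprintf(
    "two_way_fit: %d probes x %d arrays, overall %.4g, sigma2 %.4g (%s in %d sweeps)\n",
    length(x$probe_effects), length(x$array_effects), x$overall, x$sigma2,
    if (isTRUE(x$converged)) "converged" else "not converged", x$n_iterations
  ))
  invisible(x)
}

#' Residual mean squared error of a two-way fit
#'
#' Sum of squared residuals divided by the two-way ANOVA residual degrees of
#' freedom `(P - 1) * (T - 1)`.
#'
#' @param fit a `"two_way_fit"`.
#' @return nonnegative scalar.
#' @export
compute_mse <- function(fit) {
  stopifnot(inherits(fit, "two_way_fit"))
  P <- nrow(fit$residuals)
  T_ <- ncol(fit$residuals)
  if (P < 2L || T_ < 2L) {
    stop("MSE requires P >= 2 and T >= 2 (no residual degrees of freedom)")
  }
  sum(fit$residuals^2) / ((P - 1) * (T_ - 1))
}

#' Fit median polish to every gene of a probe-level dataset
#'
#' One independent two-way fit per gene, in `gene_ids` order. The returned
#' collection also records the dataset's dimensions and time labels so that
#' bootstrap replicates can be regenerated from the fits alone.
#'
#' @param dataset a `"probe_dataset"` on the log2 scale.
#' @param max_iter,tol passed to [fit_median_polish()].
#' @return An object of class `"gene_fit_collection"`: `fits` (list of
#'   `"two_way_fit"`), `gene_ids`, `time_points`.
#' @export
fit_all_genes <- function(dataset, max_iter = 10L, tol = 1e-4) {
  validate_probe_dataset(dataset)
  if (!dataset$is_log_scale) stop("dataset must be on the log2 scale")
  G <- pld_dim(dataset)[1L]
  fits <- vector("list", G)
  for (g in seq_len(G)) {
    fits[[g]] <- tryCatch(
      fit_median_polish(gene_matrix(dataset, g), max_iter, tol),
      error = function(e) {
        stop(sprintf("gene '%s': %s", dataset$gene_ids[g], conditionMessage(e)))
      }
    )
  }
  structure(
    list(
      fits = fits,
      gene_ids = dataset$gene_ids,
      time_points = dataset$time_points
    ),
    class = "gene_fit_collection"
  )
}

#' @export
print.gene_fit_collection <- function(x, ...) {
  cat(sprintf(
    "gene_fit_collection: %d genes, %d probes x %d arrays\n",
    length(x$fits), length(x$fits[[1L]]$probe_effects),
    length(x$fits[[1L]]$array_effects)
  ))
  invisible(x)
}

#' Summarize probe-level data into gene-level expression
#'
#' RMA-style summarization: per gene, a median polish is fit and the
#' expression at time t is `overall + array_effects[t]`, i.e. the probe
#' effects and residuals are swept out.
#'
#' @param normalized a `"probe_dataset"` on the log2 scale (typically after
#'   normalization).
#' @param max_iter,tol passed to [fit_median_polish()].
#' @return an `"expression_matrix"` (G x T, log2).
#' @export
summarize_expression <- function(normalized, max_iter = 10L, tol = 1e-4) {
  fits <- fit_all_genes(normalized, max_iter, tol)
  d <- pld_dim(normalized)
  vals <- matrix(NA_real_, d[1L], d[3L])
  for (g in seq_len(d[1L])) {
    f <- fits$fits[[g]]
    vals[g, ] <- f$overall + f$array_effects
  }
  expression_matrix(vals, normalized$gene_ids, normalized$time_points)
}
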
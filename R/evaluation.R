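# Rhythmicity calling and the cross-normalization comparison machinery:
# pairwise Spearman/Pearson correlations and call concordance for the
# standard measure M versus the robust measure M_Robust, typically on the
# union-rhythmic gene subset (genes called rhythmic under at least one
# normalization method).

#' Call genes rhythmic by thresholding a score vector
#'
#' A gene is declared rhythmic when its measure reaches the threshold
#' (inclusive). The default threshold 0.99 corresponds to a 1% significance
#' level on the underlying adjusted p-value.
#'
#' @param scores numeric vector of per-gene measures.
#' @param threshold scalar in (0, 1).
#' @return logical vector of rhythmicity calls.
#' @export
call_rhythmic <- function(scores, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    threshold <= 0 || threshold >= 1) {
    stop("threshold must be a scalar in (0, 1)")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  scores >= threshold
}

#' Percent concordance of two call vectors
#'
#' `100 * (genes with identical rhythmic/non-rhythmic calls) / genes`.
#'
#' @param calls_a,calls_b logical vectors of equal length.
#' @return percentage in [0, 100].
#' @export
concordance_percent <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop("call vectors differ in length")
  100 * mean(calls_a == calls_b)
}

#' Pairwise correlation matrix of score vectors
#'
#' @param score_vectors named list (one score vector per normalization
#'   method), all aligned on the same genes, at least 2 methods and 3 genes.
#' @param kind `"spearman"` or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal; undefined
#'   correlations (zero-variance vectors) are `NA` with a warning.
#' @export
correlation_matrix <- function(score_vectors, kind = c("spearman", "pearson")) {
  kind <- match.arg(kind)
  if (length(score_vectors) < 2L) stop("need at least two score vectors")
  lens <- lengths(score_vectors)
  if (length(unique(lens)) != 1L) stop("score vectors not aligned")
  if (lens[1L] < 3L) stop("need at least 3 genes")
  m <- do.call(cbind, score_vectors)
  cc <- suppressWarnings(cor(m, method = kind))
  diag(cc) <- 1
  if (anyNA(cc)) warning("zero-variance score vector: undefined correlations reported as NA")
  cc
}

#' Union-rhythmic gene subset
#'
#' Genes whose measure reaches the threshold under at least one
#' normalization method -- the subset the cross-normalization comparisons
#' are restricted to.
#'
#' @param score_vectors named list of aligned score vectors.
#' @param threshold call threshold in (0, 1).
#' @return logical vector: `TRUE` for genes in the union-rhythmic subset.
#' @export
select_union_rhythmic <- function(score_vectors, threshold = 0.99) {
  calls <- lapply(score_vectors, call_rhythmic, threshold = threshold)
  Reduce(`|`, calls)
}

#' Cross-normalization robustness report
#'
#' For every unordered pair of normalization methods, computes Spearman and
#' Pearson correlations and percent call concordance for the standard
#' measure and for the robust measure, plus their differences. By default
#' the comparison is restricted to the union-rhythmic subset (genes with
#' standard measure >= threshold under at least one method).
#'
#' @param standard named list of standard-measure vectors (one per
#'   normalization method).
#' @param robust named list of robust-measure vectors, same names and genes.
#' @param threshold call threshold in (0, 1).
#' @param union_only restrict to the union-rhythmic subset (`TRUE`, default)
#'   or use all genes.
#' @return data.frame with columns `pair`, `metric`
#'   (`spearman|pearson|concordance`), `standard_value`, `robust_value`,
#'   `delta`; one row per pair and metric.
#' @export
robustness_report <- function(standard, robust, threshold = 0.99,
                              union_only = TRUE) {
  if (!identical(sort(names(standard)), sort(names(robust)))) {
    stop("standard and robust maps must cover the same normalization methods")
  }
  methods <- names(standard)
  robust <- robust[methods]
  keep <- if (union_only) {
    select_union_rhythmic(standard, threshold)
  } else {
    rep(TRUE, length(standard[[1L]]))
  }
  if (sum(keep) < 3L) stop("fewer than 3 genes in the comparison subset")
  std_s <- lapply(standard, `[`, keep)
  rob_s <- lapply(robust, `[`, keep)

  rows <- list()
  for (i in seq_along(methods)[-length(methods)]) {
    for (j in seq((i + 1L), length(methods))) {
      pair <- paste(methods[i], methods[j], sep = ":")
      for (metric in c("spearman", "pearson", "concordance")) {
        if (metric == "concordance") {
          sv <- concordance_percent(
            call_rhythmic(std_s[[i]], threshold),
            call_rhythmic(std_s[[j]], threshold)
          )
          rv <- concordance_percent(
            call_rhythmic(rob_s[[i]], threshold),
            call_rhythmic(rob_s[[j]], threshold)
          )
        } else {
          sv <- suppressWarnings(cor(std_s[[i]], std_s[[j]], method = metric))
          rv <- suppressWarnings(cor(rob_s[[i]], rob_s[[j]], method = metric))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pair, metric = metric,
          standard_value = sv, robust_value = rv, delta = rv - sv,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
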
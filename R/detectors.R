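# Per-gene rhythmicity detectors on summarized expression.  Two bespoke
# reference detectors are provided -- a cosinor F-test and a nonparametric
# rank-template test -- and any external tool's per-gene p-values can be
# plugged in through the registry, since the measures downstream only need a
# raw p-value per gene.

#' Describe a rhythmicity detector
#'
#' @param name registered detector name; built-ins are `"cosinor_f"` and
#'   `"rank_template"`.
#' @param period test period in time-label units. For a design spanning two
#'   full cycles the natural default is half the time range.
#' @param parameters method-specific settings (e.g. `n_phases` for
#'   `"rank_template"`).
#' @return an object of class `"detector_method"`.
#' @export
detector_method <- function(name, period, parameters = list()) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  if (!is.numeric(period) || period <= 0) stop("period must be positive")
  structure(list(name = name, period = period, parameters = parameters),
    class = "detector_method"
  )
}

#' Register a rhythmicity detector
#'
#' Plug-ins share the built-ins' contract: `fun(expr, period, params)` takes
#' an `"expression_matrix"` and returns a vector of per-gene raw p-values in
#' `[0, 1]`, aligned with `expr$gene_ids`.
#'
#' @param name detector name.
#' @param fun function of `(expr, period, params)`.
#' @return `name`, invisibly.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .registries$detector)
  invisible(name)
}

#' Names of registered detectors
#' @return character vector.
#' @export
list_detectors <- function() {
  sort(ls(.registries$detector))
}

#' Build a detector from an external p-value table
#'
#' Reads a TSV with header `gene_id<TAB>raw_pvalue` (e.g. exported from a
#' published rhythmicity tool) and returns a detector function whose gene
#' set must match the expression matrix exactly.
#'
#' @param path TSV path.
#' @return a function usable with [register_detector()].
#' @export
external_pvalue_detector <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!identical(names(tab), c("gene_id", "raw_pvalue"))) {
    stop("expected header: gene_id\traw_pvalue")
  }
  function(expr, period, params) {
    idx <- match(expr$gene_ids, tab$gene_id)
    if (any(is.na(idx)) || nrow(tab) != length(idx)) {
      stop("external p-value table does not match the expression matrix genes")
    }
    as.numeric(tab$raw_pvalue[idx])
  }
}

#' Cosinor F-test for rhythmicity
#'
#' Per gene, least-squares fit of
#' `y_t = m + A cos(2 pi t / period) + B sin(2 pi t / period)` against the
#' intercept-only model; the p-value comes from the F statistic with
#' `(2, T - 3)` degrees of freedom. Zero-variance series get p = 1 by
#' convention.
#'
#' @param expr an `"expression_matrix"` with `T >= 4` time points.
#' @param period test period, in `(2, T]` time-label units.
#' @return numeric vector of raw p-values, aligned with `expr$gene_ids`.
#' @export
detect_cosinor <- function(expr, period) {
  stopifnot(inherits(expr, "expression_matrix"))
  tt <- expr$time_points
  T_ <- length(tt)
  if (T_ < 4L) stop("cosinor needs T >= 4 time points")
  if (period <= 2 || period > diff(range(tt)) + (tt[2L] - tt[1L])) {
    stop("period must lie in (2, T] time-label units")
  }
  Y <- t(expr$values) # T x G
  X <- cbind(1, cos(2 * pi * tt / period), sin(2 * pi * tt / period))
  fitted <- X %*% qr.solve(X, Y)
  rss1 <- colSums((Y - fitted)^2)
  rss0 <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / (T_ - 3))
  p <- pf(Fstat, 2, T_ - 3, lower.tail = FALSE)
  p[rss1 == 0 & rss0 > 0] <- 0 # perfect sinusoidal fit
  p[rss0 <= .Machine$double.eps * T_] <- 1 # flat series
  p[!is.finite(p)] <- 1
  unname(p)
}

#' Rank-template test for rhythmicity
#'
#' Per gene, Kendall rank correlation between the series and cosine
#' reference curves at `n_phases` equispaced phase shifts; per-phase
#' two-sided p-values from the normal null of the rank statistic, combined
#' by Bonferroni (`min p * n_phases`, capped at 1). Depends only on ranks,
#' so it is invariant to any strictly monotone per-gene transform. All-tied
#' series get p = 1.
#'
#' @param expr an `"expression_matrix"` with `T >= 8` time points.
#' @param period test period in time-label units.
#' @param n_phases number of phase-shifted templates (>= 2).
#' @return numeric vector of raw p-values, aligned with `expr$gene_ids`.
#' @export
detect_rank_template <- function(expr, period, n_phases = 8L) {
  stopifnot(inherits(expr, "expression_matrix"))
  tt <- expr$time_points
  if (length(tt) < 8L) stop("rank-template test needs T >= 8 time points")
  n_phases <- as.integer(n_phases)
  if (n_phases < 2L) stop("need n_phases >= 2")
  shifts <- period * (seq_len(n_phases) - 1L) / n_phases
  templates <- vapply(
    shifts, function(ph) cos(2 * pi * (tt - ph) / period),
    numeric(length(tt))
  )
  p <- apply(expr$values, 1L, function(y) {
    if (diff(range(y)) == 0) {
      return(1)
    }
    pk <- vapply(seq_len(n_phases), function(k) {
      suppressWarnings(
        cor.test(y, templates[, k], method = "kendall", exact = FALSE)$p.value
      )
    }, numeric(1L))
    min(min(pk, na.rm = TRUE) * n_phases, 1)
  })
  unname(p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical BH: sort ascending, multiply the k-th order statistic by
#' `m / k`, enforce monotonicity by cumulative minima from the largest, cap
#' at 1, return in original order.
#'
#' @param raw_pvalues numeric vector with values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(raw_pvalues) {
  if (!is.numeric(raw_pvalues) || any(!is.finite(raw_pvalues)) ||
    any(raw_pvalues < 0) || any(raw_pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  p.adjust(raw_pvalues, method = "BH")
}

#' Run a detector and adjust its p-values
#'
#' Dispatches to the registered detector, floors raw p-values of exactly 0
#' at 1e-300, and applies Benjamini-Hochberg adjustment across all genes.
#'
#' @param expr an `"expression_matrix"`.
#' @param method a `"detector_method"`.
#' @return an object of class `"detector_result"`: `raw_pvalues`,
#'   `adjusted_pvalues`, `gene_ids`, `detector`.
#' @export
run_detector <- function(expr, method) {
  stopifnot(inherits(expr, "expression_matrix"))
  stopifnot(inherits(method, "detector_method"))
  fun <- mget(method$name,
    envir = .registries$detector,
    ifnotfound = list(NULL)
  )[[1L]]
  if (is.null(fun)) stop(sprintf("unknown detector '%s'", method$name))
  raw <- as.numeric(fun(expr, method$period, method$parameters))
  if (length(raw) != length(expr$gene_ids)) {
    stop("detector returned wrong number of p-values")
  }
  raw <- pmax(raw, 1e-300)
  structure(
    list(
      raw_pvalues = raw,
      adjusted_pvalues = adjust_bh(raw),
      gene_ids = expr$gene_ids,
      detector = method
    ),
    class = "detector_result"
  )
}
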
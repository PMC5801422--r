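# Probe-level normalization: removal of array-to-array technical variation.
# All methods act on the (G*P) x T matrix whose columns are arrays, on the
# log2 scale (constant scaling internally exponentiates, scales and re-logs).
# Methods are pluggable through a registry keyed by name.

#' Describe a normalization method
#'
#' @param name registered method name; built-ins are `"none"`, `"quantile"`,
#'   `"constant"`, `"cyclic_loess"`, `"invariant_set"`.
#' @param parameters named list of method-specific settings (e.g. `span`,
#'   `max_cycles`, `tol` for cyclic loess; `baseline`, `rank_tol` for
#'   invariant set; `baseline` for constant).
#' @return an object of class `"normalization_method"`.
#' @export
normalization_method <- function(name, parameters = list()) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  structure(list(name = name, parameters = parameters),
    class = "normalization_method"
  )
}

#' Register a normalization method
#'
#' Plug-in methods share the built-ins' contract: `fun(m, params)` takes the
#' `N x T` log2 matrix and the method's parameter list and returns a matrix
#' of identical shape with rows (probes) in unchanged order.
#'
#' @param name method name.
#' @param fun function of `(m, params)`.
#' @return `name`, invisibly.
#' @export
register_normalization <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .registries$normalization)
  invisible(name)
}

#' Names of registered normalization methods
#' @return character vector.
#' @export
list_normalizations <- function() {
  sort(ls(.registries$normalization))
}

#' Normalize a probe-level dataset
#'
#' Stacks the dataset into its `(G * P) x T` probe-by-array matrix, applies
#' the named method, and restores the array layout. Gene, probe and time
#' metadata are preserved; method `"none"` is the identity.
#'
#' @param dataset a `"probe_dataset"` on the log2 scale.
#' @param method a `"normalization_method"` or a method name string.
#' @return a normalized `"probe_dataset"`.
#' @export
normalize_dataset <- function(dataset, method) {
  validate_probe_dataset(dataset)
  if (!dataset$is_log_scale) stop("dataset must be on the log2 scale")
  if (is.character(method)) method <- normalization_method(method)
  stopifnot(inherits(method, "normalization_method"))
  fun <- mget(method$name,
    envir = .registries$normalization,
    ifnotfound = list(NULL)
  )[[1L]]
  if (is.null(fun)) {
    stop(sprintf("unknown normalization method '%s'", method$name))
  }
  d <- pld_dim(dataset)
  m <- matrix(dataset$intensities, d[1L] * d[2L], d[3L])
  out <- fun(m, method$parameters)
  if (!identical(dim(out), dim(m))) {
    stop("normalization method changed the matrix shape")
  }
  probe_dataset(
    array(out, dim = d), dataset$gene_ids, dataset$time_points,
    is_log_scale = TRUE
  )
}

#' Quantile normalization
#'
#' Each column's sorted values are replaced by the across-column mean of the
#' sorted values; tied values within a column receive the mean of the
#' reference values their positions span. Afterwards all (tie-free) columns
#' share the same sorted vector.
#'
#' @param m numeric `N x T` matrix, `T >= 2`.
#' @return normalized matrix.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite entries")
  if (ncol(m) < 2L) stop("need at least two arrays")
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Constant (global scaling) normalization
#'
#' On the natural intensity scale, each column is multiplied by
#' `baseline mean / column mean`, so all arrays share the baseline's mean
#' intensity; input and output are on the log2 scale.
#'
#' @param m numeric `N x T` log2 matrix, `T >= 2`.
#' @param baseline column index, or `"global"` for the grand mean of column
#'   means.
#' @return normalized log2 matrix.
#' @export
constant_normalize <- function(m, baseline = 1L) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite entries")
  if (ncol(m) < 2L) stop("need at least two arrays")
  nat <- 2^m
  cm <- colMeans(nat)
  if (any(cm <= 0)) stop("column with non-positive natural-scale mean")
  target <- if (identical(baseline, "global")) mean(cm) else cm[[baseline]]
  log2(sweep(nat, 2L, target / cm, "*"))
}

#' Cyclic loess normalization
#'
#' For every array pair (i, j) a local-regression curve of
#' `M = col_i - col_j` on `A = (col_i + col_j) / 2` is fit and half the
#' fitted M is subtracted from `col_i` and added to `col_j`. Pair
#' adjustments are accumulated within a cycle, averaged over the `T - 1`
#' pairs each array belongs to, and applied together (synchronous update,
#' independent of pair order); full cycles repeat until the largest
#' absolute applied adjustment drops below `tol` or `max_cycles` is
#' reached.
#'
#' @param m numeric `N x T` log2 matrix, `N >= 20`, `T >= 2`.
#' @param span loess span (fraction of points).
#' @param max_cycles maximum number of full passes over all pairs.
#' @param tol convergence tolerance in log2 units.
#' @return normalized log2 matrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.4, max_cycles = 3L, tol = 0.01) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite entries")
  if (ncol(m) < 2L) stop("need at least two arrays")
  if (nrow(m) < 20L) stop("need N >= 20 probes for loess smoothing")
  T_ <- ncol(m)
  for (cycle in seq_len(max_cycles)) {
    adj <- matrix(0, nrow(m), T_)
    for (i in seq_len(T_ - 1L)) {
      for (j in seq((i + 1L), T_)) {
        A <- (m[, i] + m[, j]) / 2
        M <- m[, i] - m[, j]
        if (diff(range(A)) < 1e-10) {
          warning(sprintf("degenerate A range for array pair (%d, %d); skipped", i, j))
          next
        }
        f <- limma::loessFit(M, A, span = span)$fitted
        adj[, i] <- adj[, i] - f / 2
        adj[, j] <- adj[, j] + f / 2
      }
    }
    adj <- adj / (T_ - 1L) # mean pairwise correction per array
    m <- m + adj
    if (max(abs(adj)) < tol) break
  }
  m
}

#' Rank-invariant set normalization
#'
#' For each non-baseline array, probes whose within-set rank difference from
#' the baseline (normalized by the set size) stays below `rank_tol` are
#' iterated to a stable rank-invariant set; a monotone smooth curve through
#' that set (lowess, made monotone by isotonic regression, then linearly
#' interpolated) maps the array onto the baseline scale. When the invariant
#' set collapses below 10
#' probes the array falls back to constant normalization against the
#' baseline, with a warning.
#'
#' @param m numeric `N x T` log2 matrix, `N >= 50`, `T >= 2`.
#' @param baseline baseline column index.
#' @param rank_tol normalized rank-difference threshold.
#' @param span lowess span for the smooth monotone mapping.
#' @return normalized log2 matrix.
#' @export
invariant_set_normalize <- function(m, baseline = 1L, rank_tol = 0.01,
                                    span = 0.3) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite entries")
  if (ncol(m) < 2L) stop("need at least two arrays")
  if (nrow(m) < 50L) stop("need N >= 50 probes for invariant-set selection")
  N <- nrow(m)
  base <- m[, baseline]
  out <- m
  for (j in seq_len(ncol(m))) {
    if (j == baseline) next
    x <- m[, j]
    set <- seq_len(N)
    for (it in seq_len(50L)) {
      ns <- length(set)
      prd <- abs(rank(x[set]) - rank(base[set])) / ns
      keep <- set[prd < rank_tol]
      if (length(keep) == length(set) || length(keep) < 10L) {
        set <- keep
        break
      }
      set <- keep
    }
    if (length(set) < 10L) {
      warning(sprintf(
        "invariant set for array %d collapsed (<10 probes); falling back to constant normalization",
        j
      ))
      out[, j] <- constant_normalize(cbind(base, x), baseline = 1L)[, 2L]
      next
    }
    ord <- order(x[set])
    xs <- x[set][ord]
    ys <- base[set][ord]
    lw <- stats::lowess(xs, ys, f = span)
    smooth <- approx(lw$x, lw$y, xout = xs, rule = 2L, ties = mean)$y
    iso <- isoreg(xs, smooth)
    out[, j] <- approx(xs, iso$yf, xout = x, rule = 2L, ties = mean)$y
  }
  out
}
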
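# Data model and TSV readers/writers for probe-level and gene-level
# expression data.  A probe-level dataset is a *dense* three-way array of
# intensities indexed by (gene, probe, time); every downstream computation
# happens on the log2 scale and the reader converts natural-scale input on
# load.

#' Construct a probe-level dataset
#'
#' Container for background-corrected probe intensities of `G` genes
#' (probe sets) measured by `P` probes each over `T` arrays (time points).
#'
#' @param intensities numeric array with `dim = c(G, P, T)`; strictly
#'   positive when `is_log_scale = FALSE`, finite always.
#' @param gene_ids character vector of `G` unique gene identifiers.
#' @param time_points strictly increasing numeric vector of `T` time labels.
#'   Only the ordering is used downstream (arrays are categorical labels in
#'   the two-way model); equal spacing is assumed but not enforced.
#' @param is_log_scale logical; `TRUE` if intensities are already on the
#'   log2 scale.
#' @return An object of class `"probe_dataset"` with fields `intensities`,
#'   `gene_ids`, `time_points`, `is_log_scale`.
#' @export
probe_dataset <- function(intensities, gene_ids, time_points,
                          is_log_scale = TRUE) {
  x <- structure(
    list(
      intensities = intensities,
      gene_ids = as.character(gene_ids),
      time_points = as.numeric(time_points),
      is_log_scale = isTRUE(is_log_scale)
    ),
    class = "probe_dataset"
  )
  validate_probe_dataset(x)
  x
}

#' Validate a probe-level dataset
#'
#' Checks density (a finite intensity for every (gene, probe, time) triple),
#' positivity on the natural scale, unique gene identifiers and strictly
#' increasing time labels.
#'
#' @param x a `"probe_dataset"`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_probe_dataset <- function(x) {
  stopifnot(inherits(x, "probe_dataset"))
  d <- dim(x$intensities)
  if (is.null(d) || length(d) != 3L) {
    stop("intensities must be a 3-way array (gene x probe x time)")
  }
  if (d[1L] < 1L || d[2L] < 1L || d[3L] < 2L) {
    stop("need G >= 1 genes, P >= 1 probes and T >= 2 time points")
  }
  if (length(x$gene_ids) != d[1L]) {
    stop("gene_ids length does not match the gene dimension")
  }
  if (anyDuplicated(x$gene_ids)) stop("gene_ids must be unique")
  if (length(x$time_points) != d[3L]) {
    stop("time_points length does not match the time dimension")
  }
  if (any(diff(x$time_points) <= 0)) {
    stop("time labels must be strictly increasing")
  }
  if (!all(is.finite(x$intensities))) {
    stop("intensities must be finite (dense dataset, no missing cells)")
  }
  if (!x$is_log_scale && any(x$intensities <= 0)) {
    stop("natural-scale intensities must be strictly positive")
  }
  invisible(x)
}

#' @export
print.probe_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "probe_dataset: %d genes x %d probes x %d time points (%s scale)\n",
    d[1L], d[2L], d[3L], if (x$is_log_scale) "log2" else "natural"
  ))
  invisible(x)
}

#' Number of genes, probes and time points of a probe dataset
#' @param x a `"probe_dataset"`.
#' @return integer vector `c(G, P, T)`.
#' @export
pld_dim <- function(x) {
  stopifnot(inherits(x, "probe_dataset"))
  dim(x$intensities)
}

#' Extract the P x T intensity matrix of one gene
#' @param x a `"probe_dataset"`.
#' @param g gene index or gene id.
#' @return numeric `P x T` matrix.
#' @export
gene_matrix <- function(x, g) {
  stopifnot(inherits(x, "probe_dataset"))
  if (is.character(g)) {
    g <- match(g, x$gene_ids)
    if (is.na(g)) stop("unknown gene id")
  }
  m <- x$intensities[g, , , drop = FALSE]
  dim(m) <- dim(x$intensities)[2:3]
  m
}

#' Read a long-format probe table
#'
#' Reads a tab-separated file with header
#' `gene_id<TAB>probe_id<TAB>time_index<TAB>intensity` into a dense
#' [probe_dataset()]. Gene and probe order follow first appearance in the
#' file; time points are sorted increasingly. When `log_scale = FALSE`
#' (background-corrected intensities on the raw positive scale) the values
#' are log2-transformed on load, so the returned dataset is always on the
#' log2 scale.
#'
#' @param path file path.
#' @param log_scale logical; is the `intensity` column already log2?
#' @return a `"probe_dataset"` (log2 scale).
#' @export
read_probe_table <- function(path, log_scale = FALSE) {
  d <- read.delim(path,
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "numeric", "numeric"),
    check.names = FALSE
  )
  if (!identical(names(d), c("gene_id", "probe_id", "time_index", "intensity"))) {
    stop("expected header: gene_id\tprobe_id\ttime_index\tintensity")
  }
  if (nrow(d) == 0L) stop("empty probe table")
  if (!log_scale && any(d$intensity <= 0)) {
    stop("non-positive intensity in a natural-scale probe table")
  }

  gene_ids <- unique(d$gene_id)
  times <- sort(unique(d$time_index))
  G <- length(gene_ids)
  T_ <- length(times)

  # per-gene probe index by first appearance; P must be constant across genes
  gi <- match(d$gene_id, gene_ids)
  ti <- match(d$time_index, times)
  pi_ <- integer(nrow(d))
  P <- NA_integer_
  for (g in seq_len(G)) {
    rows_g <- which(gi == g)
    probes_g <- unique(d$probe_id[rows_g])
    if (is.na(P)) {
      P <- length(probes_g)
    } else if (length(probes_g) != P) {
      stop("ragged dataset: probes per gene is not constant")
    }
    pi_[rows_g] <- match(d$probe_id[rows_g], probes_g)
  }

  lin <- gi + G * (pi_ - 1L) + G * P * (ti - 1L)
  counts <- tabulate(lin, nbins = G * P * T_)
  if (any(counts > 1L)) stop("duplicate (gene, probe, time) row")
  if (any(counts == 0L)) {
    stop("ragged dataset: missing (gene, probe, time) combination")
  }
  arr <- array(NA_real_, dim = c(G, P, T_))
  arr[lin] <- d$intensity

  if (!log_scale) arr <- log2(arr)
  probe_dataset(arr, gene_ids, times, is_log_scale = TRUE)
}

#' Write a probe dataset as a long-format probe table
#'
#' Inverse of [read_probe_table()] (with `log_scale` matching the dataset's
#' flag). Probe identifiers are written as `p1 ... pP`.
#'
#' @param x a `"probe_dataset"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(x, path) {
  validate_probe_dataset(x)
  d <- pld_dim(x)
  G <- d[1L]; P <- d[2L]; T_ <- d[3L]
  rows <- expand.grid(t = seq_len(T_), p = seq_len(P), g = seq_len(G))
  # order: gene, then probe, then time
  rows <- rows[order(rows$g, rows$p, rows$t), , drop = FALSE]
  out <- data.frame(
    gene_id = x$gene_ids[rows$g],
    probe_id = paste0("p", rows$p),
    time_index = x$time_points[rows$t],
    intensity = x$intensities[cbind(rows$g, rows$p, rows$t)],
    stringsAsFactors = FALSE
  )
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Construct a gene x time expression matrix
#'
#' @param values numeric `G x T` matrix of log2 expression values.
#' @param gene_ids character vector of `G` unique gene identifiers.
#' @param time_points strictly increasing numeric vector of `T` time labels.
#' @return an object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, gene_ids, time_points) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids)) stop("gene_ids/value rows mismatch")
  if (ncol(values) != length(time_points)) stop("time_points/value columns mismatch")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (!all(is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(as.character(gene_ids), as.character(time_points))
  structure(
    list(
      values = values,
      gene_ids = as.character(gene_ids),
      time_points = as.numeric(time_points)
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d time points (log2)\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Header is `gene_id` followed by one column per time point, in
#' `time_points` order.
#'
#' @param x an `"expression_matrix"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  out <- data.frame(gene_id = x$gene_ids, x$values,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  names(out) <- c("gene_id", as.character(x$time_points))
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path file path.
#' @return an `"expression_matrix"`.
#' @export
read_expression_matrix <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(d)[1L] != "gene_id") stop("expected first column gene_id")
  vals <- as.matrix(d[, -1L, drop = FALSE])
  expression_matrix(vals, d$gene_id, as.numeric(names(d)[-1L]))
}
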
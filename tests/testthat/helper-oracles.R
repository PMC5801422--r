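# Independent oracles and small data builders used across tests.  Oracles
# deliberately use plain step-by-step loops so they share no code with the
# implementation they check.

# Step-by-step two-way median polish: explicit row then column sweeps,
# stopping when the sum of absolute residuals drops by less than
# tol * (initial sum + eps) or vanishes; effects median-centered at the end
# with the constants folded into the overall term.
oracle_median_polish <- function(m, max_iter = 10L, tol = 1e-4) {
  z <- m
  P <- nrow(m)
  Tn <- ncol(m)
  re <- numeric(P)
  ce <- numeric(Tn)
  init_sum <- sum(abs(z))
  oldsum <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    for (p in seq_len(P)) {
      md <- stats::median(z[p, ])
      z[p, ] <- z[p, ] - md
      re[p] <- re[p] + md
    }
    for (tt in seq_len(Tn)) {
      md <- stats::median(z[, tt])
      z[, tt] <- z[, tt] - md
      ce[tt] <- ce[tt] + md
    }
    newsum <- sum(abs(z))
    if (newsum == 0 || (oldsum - newsum) < tol * (init_sum + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  mr <- stats::median(re)
  mc <- stats::median(ce)
  list(
    overall = mr + mc, probe_effects = re - mr, array_effects = ce - mc,
    residuals = z, converged = converged, n_iterations = iters
  )
}

# Brute-force Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- (m / seq_len(m)) * ps
  if (m >= 2L) {
    for (k in (m - 1L):1L) adj[k] <- min(adj[k], adj[k + 1L])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exactly additive P x T matrix: overall + row effects + column effects.
additive_matrix <- function(overall, rows, cols) {
  overall + outer(rows, cols, "+")
}

# Tiny probe dataset built directly from an array.
make_dataset <- function(arr, gene_ids = NULL, time_points = NULL) {
  d <- dim(arr)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(d[1L]))
  if (is.null(time_points)) time_points <- seq_len(d[3L]) - 1
  probe_dataset(arr, gene_ids, time_points, is_log_scale = TRUE)
}

# Long-format probe table text for read_probe_table tests.
probe_table_lines <- function(rows) {
  c(
    "gene_id\tprobe_id\ttime_index\tintensity",
    vapply(rows, function(r) paste(r, collapse = "\t"), character(1L))
  )
}
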
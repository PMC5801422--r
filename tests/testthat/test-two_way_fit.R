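test_that("median polish decomposes additive matrices exactly", {
  m <- additive_matrix(10, c(-1, 1), c(-2, 0, 2))
  fit <- fit_median_polish(m)
  expect_equal(fit$overall, 10)
  expect_equal(fit$probe_effects, c(-1, 1))
  expect_equal(fit$array_effects, c(-2, 0, 2))
  expect_true(all(fit$residuals == 0))
  expect_true(fit$converged)

  const <- fit_median_polish(matrix(5, 3, 4))
  expect_equal(const$overall, 5)
  expect_true(all(const$probe_effects == 0))
  expect_true(all(const$array_effects == 0))
  expect_true(all(const$residuals == 0))
})

test_that("an isolated outlier lands in the residual, matching the sweep oracle", {
  m <- additive_matrix(4, c(0, 1, 2), c(-1, 0, 1))
  m[2, 3] <- m[2, 3] + 10
  fit <- fit_median_polish(m)
  orc <- oracle_median_polish(m)
  expect_equal(fit$overall, orc$overall, tolerance = 1e-9)
  expect_equal(fit$probe_effects, orc$probe_effects, tolerance = 1e-9)
  expect_equal(fit$array_effects, orc$array_effects, tolerance = 1e-9)
  expect_equal(fit$residuals, orc$residuals, tolerance = 1e-9)
  # the corruption is concentrated at the outlier cell
  expect_gt(fit$residuals[2, 3], 5)
  others <- fit$residuals
  others[2, 3] <- 0
  expect_lt(max(abs(others)), 5)
})

test_that("median polish matches the step-by-step oracle on random matrices", {
  set.seed(101)
  for (i in 1:25) {
    m <- matrix(rnorm(5 * 8), 5, 8)
    fit <- fit_median_polish(m)
    orc <- oracle_median_polish(m)
    expect_equal(fit$overall, orc$overall, tolerance = 1e-9)
    expect_equal(fit$probe_effects, orc$probe_effects, tolerance = 1e-9)
    expect_equal(fit$array_effects, orc$array_effects, tolerance = 1e-9)
    expect_equal(fit$residuals, orc$residuals, tolerance = 1e-9)
    expect_identical(fit$n_iterations, orc$n_iterations)
  }
})

test_that("reconstruction and centering invariants hold on random input", {
  set.seed(202)
  for (i in 1:20) {
    P <- sample(2:7, 1)
    Tn <- sample(3:10, 1)
    m <- matrix(rnorm(P * Tn, sd = 2), P, Tn)
    fit <- fit_median_polish(m)
    recon <- fit$overall + outer(fit$probe_effects, fit$array_effects, "+") +
      fit$residuals
    expect_equal(recon, m, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(median(fit$probe_effects), 0, tolerance = 1e-9)
    expect_equal(median(fit$array_effects), 0, tolerance = 1e-9)
    expect_gte(fit$sigma2, 0)
  }
})

test_that("median polish agrees with stats::medpolish on additive matrices", {
  set.seed(303)
  for (i in 1:10) {
    m <- additive_matrix(rnorm(1), rnorm(4), rnorm(6))
    fit <- fit_median_polish(m)
    ref <- stats::medpolish(m, trace.iter = FALSE)
    # both recover the same additive structure up to the centering convention
    expect_equal(unname(fit$residuals), unname(ref$residuals), tolerance = 1e-9)
    expect_equal(
      fit$overall + outer(fit$probe_effects, fit$array_effects, "+"),
      ref$overall + outer(ref$row, ref$col, "+"),
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("fit is invariant (up to reordering) under row/column permutations", {
  set.seed(404)
  m <- matrix(rnorm(4 * 6), 4, 6)
  pr <- sample(4)
  pc <- sample(6)
  fit <- fit_median_polish(m)
  fitp <- fit_median_polish(m[pr, pc])
  expect_equal(fitp$overall, fit$overall, tolerance = 1e-9)
  expect_equal(fitp$probe_effects, fit$probe_effects[pr], tolerance = 1e-9)
  expect_equal(fitp$array_effects, fit$array_effects[pc], tolerance = 1e-9)
  expect_equal(fitp$residuals, fit$residuals[pr, pc], tolerance = 1e-9)
})

test_that("corrupting one cell of an additive base moves effects by a bounded amount", {
  base <- additive_matrix(8, seq(-2, 2), seq(-1, 1, length.out = 5))
  ref <- fit_median_polish(base)
  for (corruption in c(0.5, 3, 50, -20)) {
    m <- base
    m[2, 4] <- m[2, 4] + corruption
    fit <- fit_median_polish(m)
    shift <- max(
      abs(fit$probe_effects - ref$probe_effects),
      abs(fit$array_effects - ref$array_effects),
      abs(fit$overall - ref$overall)
    )
    expect_lt(shift, abs(corruption) / 2)
    # the residual at the corrupted cell absorbs most of the corruption
    expect_gt(abs(fit$residuals[2, 4]), abs(corruption) / 2)
  }
})

test_that("MSE is the residual sum of squares over (P-1)(T-1)", {
  fit <- fit_median_polish(additive_matrix(1, c(0, 1), c(0, 1, 2)))
  expect_equal(compute_mse(fit), 0)

  fit$residuals <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(compute_mse(fit), 4)

  set.seed(11)
  m <- matrix(rnorm(5 * 6), 5, 6)
  f <- fit_median_polish(m)
  brute <- 0
  for (i in 1:5) for (j in 1:6) brute <- brute + f$residuals[i, j]^2
  expect_equal(compute_mse(f), brute / (4 * 5), tolerance = 1e-12)

  f1 <- fit_median_polish(matrix(rnorm(4), 1, 4))
  expect_error(compute_mse(f1), "degrees of freedom")
  expect_true(is.na(f1$sigma2))
})

test_that("non-finite input is rejected", {
  m <- matrix(rnorm(6), 2, 3)
  m[1, 1] <- NA
  expect_error(fit_median_polish(m), "finite")
})

test_that("fit_all_genes fits genes independently and in order", {
  set.seed(21)
  arr <- array(rnorm(3 * 4 * 6, mean = 7), dim = c(3, 4, 6))
  ds <- make_dataset(arr)
  coll <- fit_all_genes(ds)
  expect_length(coll$fits, 3L)
  expect_identical(coll$gene_ids, ds$gene_ids)
  for (g in 1:3) {
    single <- fit_median_polish(gene_matrix(ds, g))
    expect_equal(coll$fits[[g]], single)
  }
  # permuting the gene order permutes the fits identically
  perm <- c(3L, 1L, 2L)
  dsp <- probe_dataset(arr[perm, , ], ds$gene_ids[perm], ds$time_points)
  collp <- fit_all_genes(dsp)
  expect_equal(collp$fits, coll$fits[perm])
})

test_that("fit_all_genes recovers planted effects from noise-free data", {
  cfg <- synthetic_config(
    G = 4L, P = 5L, T = 12L, period = 6, noise_sd_range = c(0, 0), seed = 5L
  )
  fx <- median_polish_roundtrip_fixture(cfg)
  coll <- fit_all_genes(fx$dataset)
  for (g in seq_len(cfg$G)) {
    expect_equal(coll$fits[[g]]$overall, fx$fits$fits[[g]]$overall,
      tolerance = 1e-9
    )
    expect_equal(coll$fits[[g]]$probe_effects, fx$fits$fits[[g]]$probe_effects,
      tolerance = 1e-9
    )
    expect_equal(coll$fits[[g]]$array_effects, fx$fits$fits[[g]]$array_effects,
      tolerance = 1e-9
    )
    expect_equal(coll$fits[[g]]$sigma2, 0, tolerance = 1e-12)
  }
})

test_that("summarization sweeps probe effects out and keeps the time profile", {
  # P = 1: expression is the single probe series itself
  series <- sin(seq(0, 4 * pi, length.out = 12)) + 8
  ds1 <- make_dataset(array(series, dim = c(1, 1, 12)))
  expr1 <- summarize_expression(ds1)
  expect_equal(unname(expr1$values[1L, ]), series, tolerance = 1e-9)

  # probe-shifted copies of one series: expression equals the series up to a
  # constant
  shifts <- c(-1, 0, 0.5, 2)
  arr <- array(NA_real_, dim = c(1, 4, 12))
  for (p in 1:4) arr[1, p, ] <- series + shifts[p]
  expr <- summarize_expression(make_dataset(arr))
  prof <- unname(expr$values[1L, ])
  expect_equal(prof - mean(prof), series - mean(series), tolerance = 1e-9)

  # noisy gene: close to planted beta and to an independent
  # row-median-after-probe-centering oracle
  set.seed(31)
  beta <- 8 + 1.5 * cos(2 * pi * (0:23) / 12)
  pe <- rnorm(6, 0, 1)
  pe <- pe - median(pe)
  noisy <- outer(pe, beta, "+") + matrix(rnorm(6 * 24, 0, 0.05), 6, 24)
  exprn <- summarize_expression(make_dataset(array(noisy, c(1, 6, 24))))
  est <- unname(exprn$values[1L, ])
  expect_lt(max(abs(est - beta)), 0.1)
  centered <- noisy - apply(noisy, 1, median)
  oracle_est <- apply(centered, 2, median) + median(apply(noisy, 1, median))
  expect_lt(max(abs(est - oracle_est)), 0.1)
})
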
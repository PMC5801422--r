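test_that("fraction_rhythmic = 0 yields only flat genes", {
  cfg <- synthetic_config(G = 20L, P = 3L, T = 12L, period = 6,
                          fraction_rhythmic = 0, seed = 2L)
  gen <- generate_dataset(cfg)
  expect_false(any(gen$truth$is_rhythmic))
  expect_true(all(gen$truth$amplitude == 0))
})

test_that("noise-free rhythmic gene is the exact cosine on every probe", {
  cfg <- synthetic_config(
    G = 1L, P = 3L, T = 24L, period = 12, fraction_rhythmic = 1,
    probe_effect_sd = 0, noise_sd_range = c(0, 0),
    amplitude_range = c(1, 1), seed = 3L
  )
  gen <- generate_dataset(cfg)
  tr <- gen$truth
  expected <- tr$amplitude[1L] *
    cos(2 * pi * ((0:23) - tr$phase[1L]) / 12)
  for (p in 1:3) {
    series <- gene_matrix(gen$dataset, 1L)[p, ]
    expect_equal(series - mean(series), expected - mean(expected),
      tolerance = 1e-9
    )
  }
})

test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- synthetic_config(G = 10L, P = 3L, T = 12L, period = 6, seed = 7L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth, b$truth)
  cfg2 <- synthetic_config(G = 10L, P = 3L, T = 12L, period = 6, seed = 8L)
  expect_false(identical(a$dataset$intensities,
                         generate_dataset(cfg2)$dataset$intensities))
})

test_that("roundtrip fixture carries the exact decomposition", {
  cfg <- synthetic_config(
    G = 5L, P = 4L, T = 12L, period = 6, noise_sd_range = c(0, 0), seed = 13L
  )
  fx <- median_polish_roundtrip_fixture(cfg)
  coll <- fit_all_genes(fx$dataset)
  for (g in 1:5) {
    expect_equal(coll$fits[[g]]$probe_effects, fx$fits$fits[[g]]$probe_effects,
      tolerance = 1e-9
    )
    expect_equal(coll$fits[[g]]$array_effects, fx$fits$fits[[g]]$array_effects,
      tolerance = 1e-9
    )
    expect_equal(fx$fits$fits[[g]]$sigma2, 0)
    expect_equal(coll$fits[[g]]$sigma2, 0, tolerance = 1e-18)
  }
  noisy_cfg <- synthetic_config(G = 2L, P = 3L, T = 12L, period = 6)
  expect_error(median_polish_roundtrip_fixture(noisy_cfg), "noise")
})

test_that("bias injection perturbs data but never the truth", {
  cfg <- synthetic_config(G = 30L, P = 4L, T = 12L, period = 6, seed = 17L)
  gen <- generate_dataset(cfg)
  expect_identical(
    inject_array_bias(gen$dataset, "offset", 0, seed = 1L)$intensities,
    gen$dataset$intensities
  )
  for (model in c("offset", "scale", "nonlinear")) {
    biased <- inject_array_bias(gen$dataset, model, 0.4, seed = 1L)
    expect_false(identical(biased$intensities, gen$dataset$intensities))
    expect_identical(biased$gene_ids, gen$dataset$gene_ids)
    expect_identical(pld_dim(biased), pld_dim(gen$dataset))
  }
  biased_cfg <- synthetic_config(
    G = 30L, P = 4L, T = 12L, period = 6, seed = 17L,
    bias_model = "offset", bias_magnitude = 0.4
  )
  gen_biased <- generate_dataset(biased_cfg)
  expect_identical(gen_biased$truth, gen$truth)
  expect_error(inject_array_bias(gen$dataset, "wiggle", 0.4), "arg")
})

test_that("quantile normalization strips planted array offsets", {
  cfg <- synthetic_config(G = 50L, P = 4L, T = 12L, period = 6, seed = 19L)
  clean <- generate_dataset(cfg)$dataset
  biased <- inject_array_bias(clean, "offset", 0.6, seed = 21L)
  colspread <- function(ds) {
    sd(colMeans(matrix(ds$intensities, prod(pld_dim(ds)[1:2]), pld_dim(ds)[3L])))
  }
  normed <- normalize_dataset(biased, "quantile")
  expect_lt(colspread(normed), 0.2 * colspread(biased))
})

test_that("without bias normalization is near-identity at the default scale", {
  # the property concerns dense designs (many probes per array); at the
  # default 2400 probes x 48 arrays every method stays within 0.05 log2
  cfg <- synthetic_config(seed = 23L)
  ds <- generate_dataset(cfg)$dataset
  for (method in c("quantile", "constant", "invariant_set")) {
    out <- normalize_dataset(ds, method)
    expect_lt(mean(abs(out$intensities - ds$intensities)), 0.05)
  }
})

test_that("nonlinear bias decorrelates M across normalization methods", {
  cfg <- synthetic_config(seed = 29L) # G = 300, P = 8, T = 48
  clean <- generate_dataset(cfg)$dataset
  biased <- inject_array_bias(clean, "nonlinear", 0.3, seed = 31L)
  meth <- detector_method("cosinor_f", 24)
  m_for <- function(ds, n) {
    expr <- summarize_expression(normalize_dataset(ds, n))
    standard_measure(run_detector(expr, meth), n)$M
  }
  cor_clean <- cor(m_for(clean, "quantile"), m_for(clean, "constant"),
    method = "spearman"
  )
  cor_biased <- cor(m_for(biased, "quantile"), m_for(biased, "constant"),
    method = "spearman"
  )
  expect_gte(cor_clean - cor_biased, 0.05)
  # quantile normalization undoes a monotone warp; the unnormalized biased
  # data disagree with the clean data far more than the normalized ones do
  expect_lt(
    mean(abs(normalize_dataset(biased, "quantile")$intensities -
      normalize_dataset(clean, "quantile")$intensities)),
    mean(abs(biased$intensities - clean$intensities))
  )
})

test_that("asymmetric waveform sharpens peaks but keeps the period", {
  cfg <- synthetic_config(
    G = 1L, P = 1L, T = 48L, period = 24, fraction_rhythmic = 1,
    probe_effect_sd = 0, noise_sd_range = c(0, 0),
    amplitude_range = c(1, 1), waveform = "asymmetric", seed = 37L
  )
  series <- gene_matrix(generate_dataset(cfg)$dataset, 1L)[1L, ]
  # period-24 structure: the series repeats across the two cycles
  expect_equal(series[1:24], series[25:48], tolerance = 1e-9)
  # cosine cubed spends more time near the baseline than a pure cosine
  centered <- series - mean(series)
  expect_gt(mean(abs(centered) < 0.3 * max(abs(centered))), 0.4)
})

test_that("config validation rejects malformed settings", {
  expect_error(synthetic_config(fraction_rhythmic = 1.2), "fraction")
  expect_error(synthetic_config(amplitude_range = c(2, 1)), "well-ordered")
  expect_error(synthetic_config(period = 100), "period")
  expect_error(synthetic_config(G = 0L), "dimensions")
})
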
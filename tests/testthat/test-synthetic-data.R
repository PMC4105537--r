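test_that("config validation catches bad worlds", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(10, n_de = 8, n_ts = 8), "n_de \\+ n_ts")
  expect_error(sim_config(10, tissue_names = rep("HYP", 8)), "distinct")
  expect_error(sim_config(10, variance_components = c(1, -1, 1, 1, 1)),
               "nonnegative")
  expect_error(sim_config(10, n_regulators = 1, n_rewired_regulators = 2),
               "n_rewired")
})

test_that("empty and deterministic generation", {
  gen0 <- generate_dataset(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(gen0$matrix), 0L)
  expect_equal(nrow(gen0$truth$de_genes), 0L)

  g1 <- generate_dataset(sim_config(n_genes = 40, n_de = 5, n_ts = 5,
                                    n_regulators = 3,
                                    n_rewired_regulators = 1, seed = 1))
  g2 <- generate_dataset(sim_config(n_genes = 40, n_de = 5, n_ts = 5,
                                    n_regulators = 3,
                                    n_rewired_regulators = 1, seed = 1))
  expect_identical(g1, g2)
})

test_that("emitted values are finite nonnegative RPKM with full design", {
  gen <- small_dataset(n_genes = 80, seed = 3)
  expect_true(all(is.finite(gen$matrix)))
  expect_true(all(gen$matrix >= 0))
  expect_equal(dim(gen$matrix), c(80L, 8L * 2L * 4L))
  expect_setequal(colnames(gen$matrix), gen$sheet$library)
  # one library per animal x tissue
  expect_equal(anyDuplicated(gen$sheet[c("tissue", "animal")]), 0L)
})

test_that("dropping libraries emulates failed samples", {
  gen <- generate_dataset(sim_config(n_genes = 30, drop_libraries = 3,
                                     seed = 5))
  expect_equal(ncol(gen$matrix), 61L)
  expect_equal(nrow(gen$sheet), 61L)
})

test_that("planted DE genes carry the configured state shift", {
  gen <- generate_dataset(sim_config(n_genes = 500, n_de = 50,
                                     de_shift = 2.0, seed = 7))
  lg <- log2(gen$matrix)
  post <- gen$sheet$state == "POST"
  diff <- rowMeans(lg[, post]) - rowMeans(lg[, !post])
  tr <- gen$truth$de_genes
  aligned <- diff[tr$gene] * sign(tr$shift)
  # sampling sd of the mean over 50 planted genes is ~0.09 (gene x state,
  # gene x animal and residual contrasts); assert within ~3.5 sd
  expect_gt(mean(aligned), 1.68)
  expect_lt(mean(aligned), 2.32)
  # every planted gene is individually shifted in the right direction
  expect_true(all(aligned > 0.5))
})

test_that("planted TS genes are elevated only in their tissue", {
  gen <- generate_dataset(sim_config(n_genes = 200, n_ts = 16, ts_boost = 5,
                                     seed = 11))
  lg <- log2(gen$matrix)
  tr <- gen$truth$ts_genes
  for (i in seq_len(4)) {       # spot-check a few planted genes
    g <- tr$gene[i]
    own <- gen$sheet$tissue == tr$tissue[i]
    expect_gt(mean(lg[g, own]) - mean(lg[g, !own]), 2.5)
  }
})

test_that("null world has no state signal and variance decomposes", {
  vc <- c(1, 0.5, 0.25, 0.25, 0.5)
  gen <- generate_dataset(sim_config(n_genes = 2000, seed = 13,
                                     variance_components = vc,
                                     library_effect_sd = 0))
  lg <- log2(gen$matrix)
  # per-tissue sample means indistinguishable across states
  for (tt in c("HYP", "LIV")) {
    pre <- lg[, gen$sheet$tissue == tt & gen$sheet$state == "PRE"]
    post <- lg[, gen$sheet$tissue == tt & gen$sheet$state == "POST"]
    expect_gt(stats::t.test(colMeans(pre), colMeans(post))$p.value, 0.01)
  }
  # total variance decomposes into the effective components (+-20%)
  tot_true <- sum(gen$truth$true_components)
  expect_lt(abs(stats::var(as.vector(lg)) / tot_true - 1), 0.2)
})

test_that("snp table construction respects the truth split", {
  cfg <- sim_config(n_genes = 100, n_de = 10, n_ts = 10, n_snps = 40,
                    seed = 7)
  gen <- generate_dataset(cfg)
  st <- generate_snp_table(cfg, gen$truth, rownames(gen$matrix))
  expect_equal(nrow(st$snps), 40L)
  tr <- st$snps[st$snps$snp %in% st$snp_truth$snp, ]
  expect_true(all(tr$pvalue < 0.01))
  expect_true(all(tr$distance_bp == 0))
  expect_true(all(tr$gene %in% c(gen$truth$de_genes$gene,
                                 gen$truth$ts_genes$gene)))
  dec <- st$snps[!st$snps$snp %in% st$snp_truth$snp, ]
  expect_true(all(dec$pvalue > 0.01))
  expect_true(all(dec$distance_bp > 0 & dec$distance_bp <= 10000))

  cfg0 <- sim_config(n_genes = 100, n_snps = 0, seed = 7)
  expect_equal(nrow(generate_snp_table(cfg0, gen$truth,
                                       rownames(gen$matrix))$snps), 0L)
  cfg_big <- sim_config(n_genes = 10, n_snps = 31, seed = 7)
  expect_error(generate_snp_table(cfg_big, gen$truth, rownames(gen$matrix)),
               "3 x n_genes")
})

test_that("rewired regulators realize the planted wiring change", {
  cfg <- sim_config(n_genes = 300, n_de = 40, n_ts = 20, n_regulators = 6,
                    n_rewired_regulators = 2, rewire_strength = 1.0,
                    seed = 7)
  gen <- generate_dataset(cfg)
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  norm <- normalize_expression(fit, gen$sheet, allow_unconverged = TRUE)
  tr <- gen$truth
  rew <- tr$regulators$regulator[tr$regulators$rewired]
  for (rg in rew) {
    tg <- tr$regulator_targets$target[tr$regulator_targets$regulator == rg]
    sc <- state_correlations(norm, gen$sheet, rg, tg)
    expect_gte(mean(abs(sc$dw)), 0.5)
  }
})
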
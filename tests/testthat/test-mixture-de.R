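norm_fixture <- function(seed = 4) {
  gen <- generate_dataset(sim_config(n_genes = 200, n_de = 20, de_shift = 2,
                                     seed = seed))
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  list(norm = normalize_expression(fit, gen$sheet, allow_unconverged = TRUE),
       sheet = gen$sheet, truth = gen$truth)
}

test_that("de_measure is a state-mean contrast and antisymmetric", {
  fx <- norm_fixture()
  d <- de_measure(fx$norm, fx$sheet, "HYP")
  # antisymmetry under swapping state labels
  swapped <- fx$sheet
  swapped$state <- ifelse(swapped$state == "PRE", "POST", "PRE")
  expect_equal(de_measure(fx$norm, swapped, "HYP"), -d)
  # planted DE genes land near the configured shift (per-gene animal
  # noise allows a minority of stragglers)
  tr <- fx$truth$de_genes
  aligned <- d[tr$gene] * sign(tr$shift)
  expect_gt(mean(aligned), 1.6)
  expect_lt(mean(aligned), 2.4)
  expect_true(all(aligned > 0.5))
  # identical PRE and POST values give d = 0
  flat <- fx$norm
  flat[] <- rep(rowMeans(flat), ncol(flat))
  expect_true(all(abs(de_measure(flat, fx$sheet, "HYP")) < 1e-12))
  expect_error(de_measure(fx$norm, fx$sheet, "KIDNEY"), "KIDNEY")
})

test_that("mixture EM recovers a planted two-component structure", {
  set.seed(20)
  d <- c(stats::rnorm(18000, 0, 0.05), stats::rnorm(2000, 0, 1))
  fit <- fit_mixture(d, seed = 20)
  expect_gt(fit$pi0, 0.88)
  expect_lt(fit$pi0, 0.92)
  expect_lt(fit$sigma0, fit$sigma1)
  expect_true(all(fit$posterior_null >= 0 & fit$posterior_null <= 1))
  expect_equal(fit$pi0 + fit$pi1, 1, tolerance = 1e-12)
  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("mixture fit respects sign symmetry and degenerate input", {
  set.seed(8)
  d <- c(stats::rnorm(500, 0, 0.1), stats::rnorm(100, 1.5, 0.5))
  f1 <- fit_mixture(d, seed = 3)
  f2 <- fit_mixture(-d, seed = 3)
  expect_equal(f1$pi0, f2$pi0, tolerance = 1e-4)
  expect_equal(f1$mu0, -f2$mu0, tolerance = 1e-4)
  expect_equal(f1$mu1, -f2$mu1, tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)

  expect_error(fit_mixture(rep(1, 100)), "degenerate")
  expect_error(fit_mixture(stats::rnorm(10)), ">= 50")

  set.seed(9)
  single <- stats::rnorm(5000)
  fs <- suppressWarnings(fit_mixture(single, seed = 9))
  expect_true(fs$no_de_signal)
})

test_that("call_de applies the mean-posterior FDR prefix rule", {
  d <- c(a = 3, b = -2.5, c = 0.1, e = 0.05, f = -0.02)
  fake <- structure(list(posterior_null = c(a = 0.001, b = 0.004, c = 0.9,
                                            e = 0.95, f = 0.99)),
                    class = "mixture_fit")
  calls <- call_de(fake, d, fdr_target = 0.01)
  expect_setequal(calls$gene[calls$is_de], c("a", "b"))
  expect_equal(calls$direction[calls$gene == "a"], "up")
  expect_equal(calls$direction[calls$gene == "b"], "down")
  expect_lte(attr(calls, "estimated_fdr"), 0.01)
  # signed fold-change convention
  expect_equal(calls$fold_change[calls$gene == "a"], 2^3)
  expect_equal(calls$fold_change[calls$gene == "b"], -(2^2.5))

  all_null <- structure(list(posterior_null = rep(1, 5)),
                        class = "mixture_fit")
  expect_equal(sum(call_de(all_null, d)$is_de), 0L)
  expect_error(call_de(fake, d, fdr_target = 1.5), "fdr_target")
})

test_that("posterior null decreases in |d - mu0| when means coincide", {
  set.seed(5)
  d <- c(stats::rnorm(2000, 0, 0.3), stats::rnorm(500, 0, 2))
  fit <- fit_mixture(d, seed = 5)
  grid <- seq(0, 4, by = 0.1)
  p0g <- fit$pi0 * stats::dnorm(grid, fit$mu0, fit$sigma0)
  p1g <- fit$pi1 * stats::dnorm(grid, fit$mu1, fit$sigma1)
  post <- p0g / (p0g + p1g)
  expect_true(all(diff(post[grid >= abs(fit$mu0)]) < 1e-8))
})

test_that("planted DE recovery through the full normalization chain", {
  gen <- generate_dataset(sim_config(n_genes = 500, n_de = 40, de_shift = 2,
                                     seed = 21))
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  norm <- normalize_expression(fit, gen$sheet, allow_unconverged = TRUE)
  d <- de_measure(norm, gen$sheet, "PIT")
  mf <- fit_mixture(d, seed = 21)
  calls <- call_de(mf, d, fdr_target = 0.01)
  called <- calls$gene[calls$is_de]
  tp <- sum(called %in% gen$truth$de_genes$gene)
  expect_gte(tp / max(1, length(called)), 0.9)
  expect_gte(tp / nrow(gen$truth$de_genes), 0.7)
})
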
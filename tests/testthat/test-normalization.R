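make_toy <- function(m = 3, seed = 1) {
  # 2 tissues x 2 states x 2 animals-per-state = 8 libraries
  set.seed(seed)
  sheet <- expand.grid(tissue = c("A", "B"), animal = c("a1", "a2", "a3", "a4"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$state <- ifelse(sheet$animal %in% c("a1", "a2"), "PRE", "POST")
  sheet$library <- paste0("L", seq_len(nrow(sheet)))
  sheet <- sheet[, c("library", "tissue", "animal", "state")]
  mat <- matrix(rnorm(m * nrow(sheet), 5, 1), m, nrow(sheet),
                dimnames = list(paste0("g", seq_len(m)), sheet$library))
  list(mat = mat, sheet = sheet)
}

test_that("degenerate all-identical input gives a zero fit", {
  toy <- make_toy()
  toy$mat[] <- 4
  fit <- fit_mixed_model(toy$mat, toy$sheet)
  expect_true(fit$converged)
  expect_equal(unname(fit$variance_components), rep(0, 5))
  norm <- normalize_expression(fit, toy$sheet)
  expect_true(all(norm == 0))
})

test_that("solutions match a dense Henderson MME solve", {
  toy <- make_toy(m = 3, seed = 7)
  # tiny instances are near-unidentifiable: non-convergence warning is
  # expected behavior; solutions at the returned components still match
  fit <- suppressWarnings(fit_mixed_model(toy$mat, toy$sheet))
  s2 <- pmax(fit$variance_components, 1e-10)
  oracle <- dense_mme(toy$mat, toy$sheet, s2)
  expect_equal(unname(fit$mu + fit$library_effects),
               unname(oracle$library), tolerance = 1e-6)
  expect_equal(unname(fit$gene_solutions), unname(oracle$G),
               tolerance = 1e-6)
  expect_equal(unname(fit$gene_tissue_solutions), unname(oracle$GT),
               tolerance = 1e-6)
  expect_equal(unname(fit$gene_animal_solutions), unname(oracle$GA),
               tolerance = 1e-6)
  expect_equal(unname(fit$gene_state_solutions), unname(oracle$GP),
               tolerance = 1e-6)
})

test_that("REML objective is monotone and solutions shrink to mean zero", {
  gen <- small_dataset(n_genes = 60, seed = 9)
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_lt(abs(mean(fit$gene_tissue_solutions)),
            1e-6 * stats::sd(fit$gene_tissue_solutions) + 1e-12)
})

test_that("normalization is invariant to a per-library offset", {
  toy <- make_toy(m = 5, seed = 3)
  fit1 <- suppressWarnings(fit_mixed_model(toy$mat, toy$sheet))
  shifted <- toy$mat
  shifted[, 2] <- shifted[, 2] + 3   # absorbed by the library effect
  fit2 <- suppressWarnings(fit_mixed_model(shifted, toy$sheet))
  n1 <- normalize_expression(fit1, toy$sheet, allow_unconverged = TRUE)
  n2 <- normalize_expression(fit2, toy$sheet, allow_unconverged = TRUE)
  expect_equal(n1, n2, tolerance = 1e-8)
})

test_that("normalize combines solutions and validates levels", {
  toy <- make_toy(m = 1)
  fit <- fit_mixed_model(rbind(toy$mat, toy$mat + 1), toy$sheet)
  # hand-set solutions: G + GT + GA + GP
  fit$gene_solutions[] <- 1
  fit$gene_tissue_solutions[] <- 0.5
  fit$gene_animal_solutions[] <- -0.25
  fit$gene_state_solutions[] <- 2
  norm <- normalize_expression(fit, toy$sheet)
  expect_true(all(abs(norm - 3.25) < 1e-12))

  bad_sheet <- toy$sheet
  bad_sheet$tissue[1] <- "UNSEEN"
  expect_error(normalize_expression(fit, bad_sheet), "unseen")

  # libraries sharing (tissue, animal, state) get identical columns
  dup_sheet <- rbind(toy$sheet, toy$sheet[1, ])
  dup_sheet$library[9] <- "L9"
  norm2 <- normalize_expression(fit, dup_sheet)
  expect_equal(norm2[, "L9"], norm2[, "L1"], ignore_attr = TRUE)
})

test_that("empty (tissue,state) cells are rejected", {
  toy <- make_toy()
  sheet <- toy$sheet
  sheet$state[sheet$tissue == "B"] <- "PRE"    # B/POST now empty
  expect_error(fit_mixed_model(toy$mat, sheet), "B/POST")
})

test_that("clustering recovers planted tissue structure", {
  gen <- generate_dataset(sim_config(
    n_genes = 150, seed = 5,
    variance_components = c(0.2, 3, 0.1, 0.05, 0.2)))  # tissue-dominated
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  norm <- normalize_expression(fit, gen$sheet, allow_unconverged = TRUE)
  cl <- cluster_check(norm, gen$sheet)
  expect_gte(cl$agreement, 0.9)

  # permutation control: shuffled tissue labels carry no signal
  set.seed(1)
  shuf <- gen$sheet
  shuf$tissue <- sample(shuf$tissue)
  expect_lt(abs(adjusted_rand_index(cl$labels, shuf$tissue)), 0.2)

  one <- gen$sheet
  one$tissue <- "HYP"
  expect_equal(cluster_check(norm, one)$agreement, 1)
})

test_that("variance components recover the generative truth", {
  # quick version of the recovery contract (full version in acceptance)
  gen <- generate_dataset(sim_config(
    n_genes = 300, seed = 7,
    variance_components = c(1.0, 0.5, 0.25, 0.25, 0.5)))
  fit <- fit_mixed_model(log_transform(gen$matrix), gen$sheet)
  rel <- abs(fit$variance_components - gen$truth$true_components) /
    gen$truth$true_components
  expect_true(all(rel < 0.3))
})
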
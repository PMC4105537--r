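#' Simulation configuration for a two-state multi-tissue RNA-Seq design
#'
#' Describes the stated world the generator emulates: a factorial design of
#' tissues x animals with animals nested in two physiological states
#' (PRE/POST), library-level offsets, gene-factor random effects on the
#' log2 RPKM scale, and planted structure (state-shifted genes,
#' tissue-specific genes, regulators whose co-expression with their targets
#' differs between states) plus a SNP association table.
#'
#' Simulation operates on the log2 scale and exponentiates at the end.
#' The per-gene baseline log2 abundance is drawn from
#' N(baseline_mean, baseline_sd^2) so the low-expression RPKM filter is
#' exercised non-trivially.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of tissues (default 8).
#' @param n_animals_per_state animals per physiological state (default 4);
#'   animals are nested in state, one library per animal x tissue.
#' @param tissue_names distinct tissue labels of length `n_tissues`.
#' @param variance_components named or unnamed numeric of length 5:
#'   sigma2_G, sigma2_GT, sigma2_GA, sigma2_GP, sigma2_e (log2 units^2).
#' @param library_effect_sd sd of per-library offsets (log2 units).
#' @param baseline_mean,baseline_sd per-gene baseline log2 abundance.
#' @param n_de number of planted state-shifted (DE) genes.
#' @param de_shift absolute POST minus PRE shift (log2 units); planted
#'   genes alternate sign (half up-, half down-regulated).
#' @param n_ts number of planted tissue-specific genes.
#' @param ts_boost log2 boost in the planted tissue.
#' @param n_regulators number of planted regulator genes.
#' @param n_rewired_regulators regulators whose target correlations change
#'   between states.
#' @param rewire_strength target correlation shift (PRE minus POST) in
#'   [0, 2].
#' @param targets_per_regulator targets co-expressed with each regulator.
#' @param n_snps rows of the SNP association table.
#' @param drop_libraries number of libraries removed at random, emulating
#'   failed samples (default 0).
#' @param seed integer seed; a single seeded stream drives the whole run.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes,
                       n_tissues = 8L,
                       n_animals_per_state = 4L,
                       tissue_names = NULL,
                       variance_components = c(sigma2_G = 1.0, sigma2_GT = 0.5,
                                               sigma2_GA = 0.25, sigma2_GP = 0.05,
                                               sigma2_e = 0.5),
                       library_effect_sd = 0.5,
                       baseline_mean = 3, baseline_sd = 2,
                       n_de = 0L, de_shift = 2.0,
                       n_ts = 0L, ts_boost = 5.0,
                       n_regulators = 0L, n_rewired_regulators = 0L,
                       rewire_strength = 1.0,
                       targets_per_regulator = 8L,
                       n_snps = 0L,
                       drop_libraries = 0L,
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_tissues <- assert_count(n_tissues, "n_tissues", min = 1L)
  n_animals_per_state <- assert_count(n_animals_per_state,
                                      "n_animals_per_state", min = 1L)
  if (is.null(tissue_names)) {
    tissue_names <- if (n_tissues == 8L) DEFAULT_TISSUES else
      paste0("T", seq_len(n_tissues))
  }
  if (length(tissue_names) != n_tissues ||
      anyDuplicated(tissue_names)) {
    stop2("tissue_names must give ", n_tissues, " distinct labels")
  }
  if (length(variance_components) != 5L || any(variance_components < 0) ||
      any(!is.finite(variance_components))) {
    stop2("variance_components must be 5 nonnegative finite values")
  }
  names(variance_components) <- c("sigma2_G", "sigma2_GT", "sigma2_GA",
                                  "sigma2_GP", "sigma2_e")
  assert_scalar_number(library_effect_sd, "library_effect_sd", min = 0)
  assert_scalar_number(de_shift, "de_shift")
  assert_scalar_number(ts_boost, "ts_boost")
  assert_scalar_number(rewire_strength, "rewire_strength", min = 0, max = 2)
  n_de <- assert_count(n_de, "n_de")
  n_ts <- assert_count(n_ts, "n_ts")
  n_regulators <- assert_count(n_regulators, "n_regulators")
  n_rewired_regulators <- assert_count(n_rewired_regulators,
                                       "n_rewired_regulators")
  n_snps <- assert_count(n_snps, "n_snps")
  drop_libraries <- assert_count(drop_libraries, "drop_libraries")
  seed <- assert_count(seed, "seed")
  if (n_de + n_ts > n_genes) stop2("n_de + n_ts must not exceed n_genes")
  if (n_rewired_regulators > n_regulators) {
    stop2("n_rewired_regulators must not exceed n_regulators")
  }
  structure(list(
    n_genes = n_genes, n_tissues = n_tissues,
    n_animals_per_state = n_animals_per_state,
    tissue_names = as.character(tissue_names),
    variance_components = variance_components,
    library_effect_sd = library_effect_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    n_de = n_de, de_shift = de_shift,
    n_ts = n_ts, ts_boost = ts_boost,
    n_regulators = n_regulators,
    n_rewired_regulators = n_rewired_regulators,
    rewire_strength = rewire_strength,
    targets_per_regulator = assert_count(targets_per_regulator,
                                         "targets_per_regulator", min = 1L),
    n_snps = n_snps, drop_libraries = drop_libraries, seed = seed
  ), class = "sim_config")
}

# Loading on a shared animal-level factor that yields (pre-shrinkage)
# correlation r between a regulator profile with factor loading `alpha`
# and a target profile whose non-factor variance is `v`.
.factor_loading <- function(r, alpha, v) {
  if (abs(r) < 1e-12) return(0)
  c2 <- alpha^2 / (v + alpha^2)            # regulator's factor share
  u2 <- r^2 / c2
  if (u2 >= 1) u2 <- 0.99
  sign(r) * sqrt(u2 * v / (1 - u2))
}

#' Generate a synthetic multi-tissue expression data set
#'
#' Simulates log2 RPKM as
#' baseline + library offset + G + GT + GA + GP + e, plants the configured
#' differential-expression, tissue-specificity and regulator-rewiring
#' structure, and returns the RPKM matrix (2^log2 values), the sample
#' sheet, and a truth table for recovery tests.
#'
#' Regulator rewiring is planted on the animal dimension (animals are
#' nested in state, so it is the only random-effect channel through which
#' state-dependent co-expression can survive mixed-model normalization):
#' each regulator tracks a latent animal factor, and its targets load on
#' the same factor with state-dependent loadings chosen so the PRE/POST
#' target correlations differ by approximately `rewire_strength`.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (genes x libraries RPKM), `sheet`
#'   (library, tissue, animal, state), and `truth` (see Details). The
#'   truth table carries `de_genes` (gene, shift), `ts_genes` (gene,
#'   tissue), `regulators` (regulator, rewired), `regulator_targets`
#'   (regulator, target, r_pre, r_post) and the effective generative
#'   variance components (`true_components`; the gene component includes
#'   the baseline variance, which is statistically inseparable from it).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop2("config must be a sim_config")
  set.seed(config$seed, kind = "Mersenne-Twister")
  vc <- config$variance_components
  m <- config$n_genes
  tn <- config$tissue_names
  Tn <- config$n_tissues
  Aps <- config$n_animals_per_state
  A <- 2L * Aps

  animals <- paste0("A", seq_len(A))
  animal_state <- rep(STATES, each = Aps)
  grid <- expand.grid(animal = animals, tissue = tn,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- animal_state[match(grid$animal, animals)]
  grid$library <- paste(grid$tissue, grid$animal, sep = "_")
  sheet <- grid[, c("library", "tissue", "animal", "state")]
  n <- nrow(sheet)

  genes <- if (m > 0) sprintf("G%05d", seq_len(m)) else character(0)
  truth <- list(
    de_genes = data.frame(gene = character(0), shift = numeric(0)),
    ts_genes = data.frame(gene = character(0), tissue = character(0)),
    regulators = data.frame(regulator = character(0), rewired = logical(0)),
    regulator_targets = data.frame(regulator = character(0),
                                   target = character(0),
                                   r_pre = numeric(0), r_post = numeric(0)),
    true_components = c(
      sigma2_G = unname(vc["sigma2_G"]) + config$baseline_sd^2,
      vc[c("sigma2_GT", "sigma2_GA", "sigma2_GP", "sigma2_e")]
    ),
    seed = config$seed
  )

  if (m == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = n,
                  dimnames = list(character(0), sheet$library))
    return(list(matrix = mat, sheet = sheet, truth = truth))
  }

  base <- stats::rnorm(m, config$baseline_mean, config$baseline_sd)
  # Library offsets are technical; balance them within each state (as a
  # blocked design would) so they cannot masquerade as a state effect.
  L <- stats::rnorm(n, 0, config$library_effect_sd)
  lib_state <- sheet$state
  L <- L - stats::ave(L, lib_state)
  G <- stats::rnorm(m, 0, sqrt(vc["sigma2_G"]))
  GT <- matrix(stats::rnorm(m * Tn, 0, sqrt(vc["sigma2_GT"])), m, Tn,
               dimnames = list(genes, tn))
  GA <- matrix(stats::rnorm(m * A, 0, sqrt(vc["sigma2_GA"])), m, A,
               dimnames = list(genes, animals))
  GP <- matrix(stats::rnorm(m * 2L, 0, sqrt(vc["sigma2_GP"])), m, 2L,
               dimnames = list(genes, STATES))

  # Plant DE: signed shift on the POST state solution, alternating sign.
  if (config$n_de > 0L) {
    de_idx <- seq_len(config$n_de)
    shifts <- config$de_shift * rep_len(c(1, -1), config$n_de)
    GP[de_idx, "POST"] <- GP[de_idx, "POST"] + shifts
    truth$de_genes <- data.frame(gene = genes[de_idx], shift = shifts)
  }

  # Plant TS: boost one tissue's interaction, cycling through tissues.
  if (config$n_ts > 0L) {
    ts_idx <- config$n_de + seq_len(config$n_ts)
    ts_tissue <- tn[((seq_len(config$n_ts) - 1L) %% Tn) + 1L]
    GT[cbind(ts_idx, match(ts_tissue, tn))] <-
      GT[cbind(ts_idx, match(ts_tissue, tn))] + config$ts_boost
    truth$ts_genes <- data.frame(gene = genes[ts_idx], tissue = ts_tissue)
  }

  # Plant regulators on the animal dimension.
  if (config$n_regulators > 0L) {
    pool <- setdiff(seq_len(m), seq_len(config$n_de + config$n_ts))
    if (length(pool) < config$n_regulators) {
      stop2("not enough genes outside the DE/TS sets for the regulators")
    }
    reg_idx <- pool[seq_len(config$n_regulators)]
    rewired <- seq_len(config$n_regulators) <= config$n_rewired_regulators
    truth$regulators <- data.frame(regulator = genes[reg_idx],
                                   rewired = rewired)
    alpha <- 3
    s2GT <- unname(vc["sigma2_GT"])
    # A rewired regulator drives a directionally coherent set of planted
    # DE genes (that state-dependent drive is why its targets are DE).
    # Non-rewired regulators are plain genes: no planted module, so
    # their differential wiring is sampling noise only.
    de_idx <- seq_len(config$n_de)
    up_pool <- de_idx[truth$de_genes$shift > 0]
    down_pool <- de_idx[truth$de_genes$shift < 0]
    rest_pool <- c(de_idx, config$n_de + seq_len(config$n_ts))
    if (length(rest_pool) == 0L) rest_pool <- setdiff(seq_len(m), reg_idx)
    tp <- config$targets_per_regulator
    take <- function(pool, k) {
      k <- min(k, length(pool))
      if (k == 0L) integer(0) else pool[seq_len(k)]
    }
    rows <- list()
    for (r in seq_len(config$n_regulators)) {
      if (rewired[r]) {
        pool <- if (r %% 2L == 1L) up_pool else down_pool
        if (length(pool) == 0L) pool <- rest_pool
        tgt <- take(pool, tp)
        up_pool <- setdiff(up_pool, tgt)
        down_pool <- setdiff(down_pool, tgt)
        r1 <- min(0.9, config$rewire_strength)
        r2 <- max(-0.9, r1 - config$rewire_strength)
        # Alternate losers and gainers of connectivity at puberty.
        if (r %% 2L == 0L) { tmp <- r1; r1 <- r2; r2 <- tmp }
        # A regulator that rewires its module across the pubertal
        # transition is itself state-shifted, in the direction of the
        # module it drives; it is therefore part of the DE truth.
        self_shift <- if (r %% 2L == 1L) config$de_shift else -config$de_shift
        GP[reg_idx[r], "POST"] <- GP[reg_idx[r], "POST"] + self_shift
        truth$de_genes <- rbind(truth$de_genes,
                                data.frame(gene = genes[reg_idx[r]],
                                           shift = self_shift))
      } else {
        next
      }
      rest_pool <- setdiff(rest_pool, tgt)
      if (length(tgt) == 0L) next
      # Center and standardize the latent factor within each state:
      # centering prevents a spurious state contrast (pseudo-DE), and
      # fixing the realized within-state scale makes the planted
      # correlations hold as stated instead of fluctuating with the
      # chi-squared lottery of 4 animal draws per state.
      f <- stats::rnorm(A)
      f <- f - stats::ave(f, animal_state)
      f_sd <- stats::ave(f, animal_state, FUN = stats::sd)
      f <- ifelse(f_sd > 0, f / f_sd, f)
      GA[reg_idx[r], ] <- alpha * f
      b1 <- .factor_loading(r1, alpha, s2GT)
      b2 <- .factor_loading(r2, alpha, s2GT)
      loads <- ifelse(animal_state == "PRE", b1, b2)
      GA[tgt, ] <- rep(loads * f, each = length(tgt))
      rows[[r]] <- data.frame(regulator = genes[reg_idx[r]],
                              target = genes[tgt],
                              r_pre = r1, r_post = r2)
    }
    truth$regulator_targets <- do.call(rbind, rows)
  }

  ti <- match(sheet$tissue, tn)
  ki <- match(sheet$animal, animals)
  pi <- match(sheet$state, STATES)
  E <- matrix(stats::rnorm(m * n, 0, sqrt(vc["sigma2_e"])), m, n)
  log2x <- base + G + GT[, ti, drop = FALSE] + GA[, ki, drop = FALSE] +
    GP[, pi, drop = FALSE] + E
  log2x <- sweep(log2x, 2L, L, "+")
  mat <- 2^log2x
  dimnames(mat) <- list(genes, sheet$library)

  if (config$drop_libraries > 0L) {
    if (config$drop_libraries >= n) stop2("cannot drop all libraries")
    drop <- sample(n, config$drop_libraries)
    mat <- mat[, -drop, drop = FALSE]
    sheet <- sheet[-drop, , drop = FALSE]
    rownames(sheet) <- NULL
  }
  list(matrix = mat, sheet = sheet, truth = truth)
}

#' Generate a SNP association table tied to planted truth
#'
#' About 70% of rows ("truth" SNPs) point at planted DE/TS genes with
#' distance 0 (within gene) and p-values below 0.01; the remainder are
#' decoys pointing at random genes at 1-10,000 bp with p-values above
#' 0.01. Truth rows are recorded in the returned `snp_truth` table.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [generate_dataset()] run with the same
#'   config.
#' @param gene_ids gene universe of the emitted expression matrix.
#' @return list with `snps` (snp, chrom, pos, trait, pvalue, gene,
#'   distance_bp, side) and `snp_truth` (snp, gene, trait, within_gene).
#' @export
generate_snp_table <- function(config, truth, gene_ids) {
  if (!inherits(config, "sim_config")) stop2("config must be a sim_config")
  n_snps <- config$n_snps
  if (n_snps > 3L * config$n_genes) {
    stop2("n_snps must not exceed 3 x n_genes")
  }
  empty <- data.frame(snp = character(0), chrom = integer(0),
                      pos = integer(0), trait = character(0),
                      pvalue = numeric(0), gene = character(0),
                      distance_bp = numeric(0), side = character(0))
  if (n_snps == 0L) {
    return(list(snps = empty,
                snp_truth = data.frame(snp = character(0), gene = character(0),
                                       trait = character(0),
                                       within_gene = logical(0))))
  }
  set.seed(config$seed + 104729L, kind = "Mersenne-Twister")
  planted <- unique(c(truth$de_genes$gene, truth$ts_genes$gene))
  planted <- intersect(planted, gene_ids)
  n_truth <- if (length(planted)) round(0.7 * n_snps) else 0L
  n_decoy <- n_snps - n_truth

  snp_id <- sprintf("rs%07d", sample.int(9999999L, n_snps))
  chrom <- sample.int(29L, n_snps, replace = TRUE)
  pos <- sample.int(120000000L, n_snps, replace = TRUE)
  trait <- sample(TRAITS, n_snps, replace = TRUE)

  gene <- character(n_snps)
  dist <- numeric(n_snps)
  side <- character(n_snps)
  pval <- numeric(n_snps)
  if (n_truth > 0L) {
    gene[seq_len(n_truth)] <- sample(planted, n_truth,
                                     replace = n_truth > length(planted))
    dist[seq_len(n_truth)] <- 0
    side[seq_len(n_truth)] <- "within"
    pval[seq_len(n_truth)] <- stats::runif(n_truth, 1e-6, 0.0099)
  }
  if (n_decoy > 0L) {
    i <- n_truth + seq_len(n_decoy)
    gene[i] <- sample(gene_ids, n_decoy, replace = n_decoy > length(gene_ids))
    dist[i] <- ceiling(stats::runif(n_decoy, 0, 10000))
    side[i] <- sample(c("upstream", "downstream"), n_decoy, replace = TRUE)
    pval[i] <- stats::runif(n_decoy, 0.0101, 1)
  }
  snps <- data.frame(snp = snp_id, chrom = chrom, pos = pos, trait = trait,
                     pvalue = pval, gene = gene, distance_bp = dist,
                     side = side)
  snp_truth <- snps[seq_len(n_truth), c("snp", "gene", "trait")]
  snp_truth$within_gene <- TRUE
  rownames(snp_truth) <- NULL
  list(snps = snps, snp_truth = snp_truth)
}
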
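PIPELINE_STAGES <- c("filter", "normalize", "de", "ts", "rif", "networks",
                     "delta", "gwas")

.STAGE_DEPS <- list(
  filter = character(0),
  normalize = "filter",
  de = "normalize",
  ts = "filter",
  rif = c("de", "ts"),
  networks = c("de", "ts", "rif"),
  delta = "networks",
  gwas = c("de", "ts")
)

#' Pipeline configuration
#'
#' Bundles the input source (a [sim_config()] for simulate mode, or file
#' paths for ingest mode), the analysis thresholds and the stage
#' toggles. All thresholds default to the pipeline's canonical values:
#' RPKM detection 0.2, mixture-model FDR 0.01, 1000 tissue-specificity
#' permutations, GWAS p < 0.01 within 10 kb, hubs at 2 SD, RIF
#' significance at |z| >= 1.96.
#'
#' @param sim a `sim_config` for simulate mode (or NULL).
#' @param matrix_path,sheet_path,snp_path,tf_path input files for ingest
#'   mode; `tf_path` is a one-id-per-line TF list, `snp_path` a SNP
#'   association table.
#' @param outdir output directory (created if missing).
#' @param seed integer master seed; per-stage sub-seeds are derived
#'   deterministically so disabling one stage cannot shift another
#'   stage's random stream.
#' @param stages stages to run (dependencies are auto-enabled);
#'   default all.
#' @param rpkm_threshold,fdr_target,ts_permutations,gwas_p,gwas_dist,hub_sd,rif_z
#'   analysis thresholds.
#' @param subnet_tissues tissues for the DE subnetwork stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, matrix_path = NULL,
                            sheet_path = NULL, snp_path = NULL,
                            tf_path = NULL, outdir = tempfile("pubnet_run_"),
                            seed = 1L, stages = PIPELINE_STAGES,
                            rpkm_threshold = 0.2, fdr_target = 0.01,
                            ts_permutations = 1000L, gwas_p = 0.01,
                            gwas_dist = 10000, hub_sd = 2, rif_z = 1.96,
                            subnet_tissues = c("HYP", "PIT")) {
  if (is.null(sim) && (is.null(matrix_path) || is.null(sheet_path))) {
    stop2("either a sim config or matrix/sheet paths are required")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    stop2("sim must be a sim_config")
  }
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  assert_scalar_number(rpkm_threshold, "rpkm_threshold", min = 1e-12)
  assert_scalar_number(fdr_target, "fdr_target", min = 1e-12, max = 1)
  ts_permutations <- assert_count(ts_permutations, "ts_permutations", min = 1L)
  assert_scalar_number(gwas_p, "gwas_p", min = 0, max = 1)
  assert_scalar_number(gwas_dist, "gwas_dist", min = 0)
  assert_scalar_number(hub_sd, "hub_sd", min = 0)
  assert_scalar_number(rif_z, "rif_z", min = 0)
  seed <- assert_count(seed, "seed")
  structure(list(sim = sim, matrix_path = matrix_path,
                 sheet_path = sheet_path, snp_path = snp_path,
                 tf_path = tf_path, outdir = outdir, seed = seed,
                 stages = stages, rpkm_threshold = rpkm_threshold,
                 fdr_target = fdr_target, ts_permutations = ts_permutations,
                 gwas_p = gwas_p, gwas_dist = gwas_dist, hub_sd = hub_sd,
                 rif_z = rif_z, subnet_tissues = subnet_tissues),
            class = "pipeline_config")
}

# Close a stage selection over dependencies; returns stages in run order.
.close_stages <- function(stages, log = NULL) {
  enabled <- stages
  repeat {
    need <- unique(unlist(.STAGE_DEPS[enabled]))
    add <- setdiff(need, enabled)
    if (!length(add)) break
    if (!is.null(log)) log("auto-enabling prerequisite stage(s): ",
                           paste(add, collapse = ", "))
    enabled <- c(enabled, add)
  }
  intersect(PIPELINE_STAGES, enabled)
}

# Deterministic sub-seed per stage, independent of which stages run.
.stage_seed <- function(seed, stage) {
  (seed + 7919L * match(stage, c("simulate", PIPELINE_STAGES))) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate/ingest,
#' expressed-gene filter + log transform, mixed-model normalization
#' (with clustering check), per-tissue mixture-model DE, entropy
#' tissue specificity, RIF regulator scoring and nine-criteria ranking,
#' PCIT networks per state, network comparison + best-trio expansion +
#' subnetwork extraction, and GWAS integration. All tabular outputs are
#' written tab-delimited under `config$outdir`; networks additionally in
#' SIF. Re-running with the same config reproduces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return run manifest: list with `seed`, `stages`, `counts` (per-stage
#'   row counts), `files` (data.frame file/rows/md5) and the in-memory
#'   `results`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop2("config must be a pipeline_config")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message("[pubnet] ", msg)
  }
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(config$outdir, paste0(name, ".failed"))
      writeLines(conditionMessage(e), marker)
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  stages <- .close_stages(config$stages, logf)
  logf("stages: ", paste(stages, collapse = ", "))
  res <- list()
  counts <- list()
  out <- function(name) file.path(config$outdir, name)

  # -- input: simulate or ingest ------------------------------------------
  if (!is.null(config$sim)) {
    stage_wrap("simulate", {
      sim <- config$sim
      gen <- generate_dataset(sim)
      res$truth <- gen$truth
      res$matrix <- gen$matrix
      res$sheet <- gen$sheet
      if (sim$n_snps > 0L) {
        st <- generate_snp_table(sim, gen$truth, rownames(gen$matrix))
        res$snps <- st$snps
        res$snp_truth <- st$snp_truth
      }
      res$tf_ids <- gen$truth$regulators$regulator
      write_expression(gen$matrix, gen$sheet, out("expression.tsv"),
                       out("sample_sheet.tsv"))
      logf("simulated ", nrow(gen$matrix), " genes x ", ncol(gen$matrix),
           " libraries (seed ", sim$seed, ")")
    })
  } else {
    stage_wrap("ingest", {
      inp <- read_expression(config$matrix_path, config$sheet_path)
      res$matrix <- inp$matrix
      res$sheet <- inp$sheet
      if (!is.null(config$snp_path)) res$snps <- read_snp_table(config$snp_path)
      if (!is.null(config$tf_path)) {
        res$tf_ids <- readLines(config$tf_path)
      } else {
        res$tf_ids <- character(0)
      }
      logf("read ", nrow(inp$matrix), " genes x ", ncol(inp$matrix),
           " libraries")
    })
  }

  if ("filter" %in% stages) {
    stage_wrap("filter", {
      res$expressed <- filter_expressed(res$matrix, res$sheet,
                                         config$rpkm_threshold)
      res$logmat <- log_transform(res$matrix[res$expressed, , drop = FALSE],
                                   floor = config$rpkm_threshold)
      counts$expressed <- length(res$expressed)
      logf(length(res$expressed), " of ", nrow(res$matrix),
           " genes pass RPKM >= ", config$rpkm_threshold)
    })
  }

  if ("normalize" %in% stages) {
    stage_wrap("normalize", {
      fit <- fit_mixed_model(res$logmat, res$sheet)
      res$fit <- fit
      res$norm <- normalize_expression(fit, res$sheet,
                                        allow_unconverged = TRUE)
      cl <- cluster_check(res$norm, res$sheet)
      res$cluster <- cl
      comp <- data.frame(component = names(fit$variance_components),
                         estimate = as.numeric(fit$variance_components))
      comp <- rbind(comp,
                    data.frame(component = c("n_iterations", "converged"),
                               estimate = c(fit$n_reml_iterations,
                                            as.numeric(fit$converged))))
      write_tsv(comp, out("model_fit.tsv"))
      nm <- data.frame(gene = rownames(res$norm), res$norm,
                       check.names = FALSE)
      write_tsv(nm, out("normalized.tsv"))
      write_tsv(data.frame(library = names(cl$labels) %||% colnames(res$norm),
                           cluster = as.integer(cl$labels)),
                out("clusters.tsv"))
      logf("REML ", fit$n_reml_iterations, " iterations, converged = ",
           fit$converged, "; tissue-cluster agreement = ",
           round(cl$agreement, 3))
    })
  }

  if ("de" %in% stages) {
    stage_wrap("de", {
      tiss <- sort(unique(res$sheet$tissue))
      de_list <- lapply(seq_along(tiss), function(i) {
        d <- de_measure(res$norm, res$sheet, tiss[i])
        fit <- fit_mixture(d, seed = .stage_seed(config$seed, "de") + i)
        calls <- call_de(fit, d, fdr_target = config$fdr_target)
        calls$tissue <- tiss[i]
        calls
      })
      res$de_calls <- do.call(rbind, de_list)
      write_tsv(res$de_calls[, c("gene", "tissue", "d", "fold_change",
                                 "posterior_null", "is_de", "direction")],
                out("de_calls.tsv"))
      counts$de_genes <- length(unique(res$de_calls$gene[res$de_calls$is_de]))
      logf(counts$de_genes, " DE genes at mixture FDR < ", config$fdr_target)
    })
  }

  if ("ts" %in% stages) {
    stage_wrap("ts", {
      mat <- res$matrix[res$expressed, , drop = FALSE]
      res$ts_calls <- call_ts(mat, res$sheet,
                               n_perm = config$ts_permutations,
                               seed = .stage_seed(config$seed, "ts"))
      write_tsv(as.data.frame(res$ts_calls), out("ts_calls.tsv"))
      counts$ts_genes <- sum(res$ts_calls$is_ts)
      logf(counts$ts_genes, " TS genes below entropy threshold ",
           round(res$ts_calls$threshold[1], 4))
    })
  }

  de_ts_union <- function() {
    unique(c(res$de_calls$gene[res$de_calls$is_de],
             res$ts_calls$gene[res$ts_calls$is_ts]))
  }

  if ("rif" %in% stages) {
    stage_wrap("rif", {
      targets <- de_ts_union()
      regs <- intersect(res$tf_ids, rownames(res$norm))
      if (length(targets) == 0L || length(regs) == 0L) {
        logf("rif skipped: no targets or no regulators")
        res$rif <- NULL
      } else {
        res$rif <- rif_analysis(res$norm, res$logmat, res$sheet,
                                 regs, targets)
        write_tsv(as.data.frame(res$rif), out("rif.tsv"))
        counts$rif_significant <- sum(res$rif$significant)
        logf(sum(res$rif$significant), " of ", nrow(res$rif),
             " regulators significant at |z| >= ", config$rif_z)
      }
    })
  }

  if ("networks" %in% stages) {
    stage_wrap("networks", {
      net_genes <- sort(unique(c(de_ts_union(),
                                 intersect(res$tf_ids, rownames(res$norm)),
                                 intersect(res$snps$gene %||% character(0),
                                           rownames(res$norm)))))
      if (length(net_genes) < 3L) stop2("fewer than 3 network genes")
      res$net_pre <- build_state_network(res$norm, res$sheet, net_genes,
                                          "PRE", rpkm = res$matrix,
                                          tf_ids = res$tf_ids)
      res$net_post <- build_state_network(res$norm, res$sheet, net_genes,
                                           "POST", rpkm = res$matrix,
                                           tf_ids = res$tf_ids)
      for (nt in list(res$net_pre, res$net_post)) {
        write_tsv(cbind(nt$edges, state = nt$state),
                  out(paste0("network_", nt$state, ".tsv")))
        write_sif(nt, out(paste0("network_", nt$state, ".sif")))
      }
      write_tsv(res$net_pre$nodes, out("node_attributes_PRE.tsv"))
      write_tsv(res$net_post$nodes, out("node_attributes_POST.tsv"))
      res$hubs <- list(PRE = find_hubs(res$net_pre, config$hub_sd),
                        POST = find_hubs(res$net_post, config$hub_sd))
      counts$edges_pre <- nrow(res$net_pre$edges)
      counts$edges_post <- nrow(res$net_post$edges)
      logf("networks: ", counts$edges_pre, " PRE edges, ",
           counts$edges_post, " POST edges over ", length(net_genes),
           " genes")
    })
  }

  if ("delta" %in% stages) {
    stage_wrap("delta", {
      res$delta <- compare_networks(res$net_pre, res$net_post)
      write_tsv(res$delta$tissue_pct, out("network_delta.tsv"))
      tfs <- intersect(res$tf_ids, res$net_post$nodes$gene)
      if (length(tfs) >= 3L) {
        res$trio <- list(PRE = best_trio(res$net_pre, tfs),
                          POST = best_trio(res$net_post, tfs))
        trio_lines <- vapply(names(res$trio), function(s) {
          tr <- res$trio[[s]]
          sprintf("%s: %s coverage=%d redundancy=%d trios=%d", s,
                  paste(tr$trio, collapse = "+"), tr$coverage,
                  tr$redundancy, tr$n_trios_examined)
        }, character(1))
        writeLines(trio_lines, out("best_trio.txt"))
        # nine-criteria TF ranking
        if (!is.null(res$rif)) {
          tiss <- sort(unique(res$sheet$tissue))
          dmat <- vapply(tiss, function(tt) de_measure(res$norm, res$sheet, tt),
                         numeric(nrow(res$norm)))
          nf <- res$delta$node_fold
          rownames(nf) <- nf$gene
          exp_pre <- tf_expansion_ability(res$net_pre, tfs)
          exp_post <- tf_expansion_ability(res$net_post, tfs)
          rr <- res$rif[match(tfs, res$rif$regulator), , drop = FALSE]
          crit <- data.frame(
            regulator = tfs,
            rif1 = rr$rif1_z, rif2 = rr$rif2_z,
            de_overall = rowMeans(dmat)[tfs],
            de_max = apply(abs(dmat[tfs, , drop = FALSE]), 1L, max),
            conn_pre = nf[tfs, "conn_pre"],
            conn_post = nf[tfs, "conn_post"],
            conn_fold = nf[tfs, "log2_fold"],
            expand_pre = exp_pre[tfs],
            expand_post = exp_post[tfs]
          )
          res$tf_ranking <- rank_regulators(crit)
          write_tsv(res$tf_ranking, out("tf_ranking.tsv"))
        }
      }
      if (!is.null(res$de_calls)) {
        sub_t <- intersect(config$subnet_tissues, unique(res$sheet$tissue))
        if (length(sub_t)) {
          res$subnetwork <- extract_subnetwork(res$net_post, res$de_calls,
                                                tissues = sub_t,
                                                tf_ids = res$tf_ids)
          write_sif(res$subnetwork, out("subnetwork.sif"))
        }
      }
      logf("delta: ", nrow(res$delta$persistent), " persistent, ",
           nrow(res$delta$disappeared), " disappeared, ",
           nrow(res$delta$emerged), " emerged")
    })
  }

  if ("gwas" %in% stages && !is.null(res$snps)) {
    stage_wrap("gwas", {
      res$loci <- integrate_gwas(res$snps, res$expressed, res$de_calls,
                                  res$ts_calls, p_max = config$gwas_p,
                                  max_dist = config$gwas_dist)
      write_tsv(res$loci, out("integrated_loci.tsv"))
      s <- summarize_loci(res$loci)
      write_tsv(data.frame(metric = c("total", names(s$per_trait),
                                      "within_gene", "uterus_endometrium",
                                      "de_flagged", "ts_flagged"),
                           value = c(s$total, as.integer(s$per_trait),
                                     s$within_gene, s$uterus_endometrium,
                                     s$de_flagged, s$ts_flagged)),
                out("loci_summary.tsv"))
      counts$loci <- s$total
      logf(s$total, " integrated loci (",
           attr(res$loci, "n_dropped_unknown_gene"),
           " SNPs dropped for unknown genes)")
    })
  }

  files <- setdiff(list.files(config$outdir), "run.log")
  manifest_files <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(file.path(config$outdir, files)))
  )
  write_tsv(manifest_files, out("manifest.tsv"))
  list(seed = config$seed, stages = stages, counts = counts,
       files = manifest_files, results = res, outdir = config$outdir)
}
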
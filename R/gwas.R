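#' Read a SNP association table
#'
#' Tab-delimited with columns snp, chrom, pos, trait, pvalue, gene,
#' distance_bp, side (within/upstream/downstream). Validates the
#' distance/side consistency (distance 0 if and only if side is
#' "within") and that p-values lie in (0, 1].
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  snps <- read_tsv(path)
  validate_snp_table(snps)
}

validate_snp_table <- function(snps) {
  need <- c("snp", "chrom", "pos", "trait", "pvalue", "gene",
            "distance_bp", "side")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop2("SNP table missing column(s): ",
                          paste(miss, collapse = ", "))
  if (nrow(snps) == 0L) return(snps)
  if (any(snps$pvalue <= 0 | snps$pvalue > 1)) {
    stop2("SNP p-values must be in (0, 1]")
  }
  if (any(snps$distance_bp < 0)) stop2("negative SNP distance")
  bad <- xor(snps$distance_bp == 0, snps$side == "within")
  if (any(bad)) {
    stop2("distance 0 must coincide with side 'within' (rows ",
          paste(utils::head(which(bad)), collapse = ", "), ")")
  }
  snps
}

#' Intersect GWAS associations with expression evidence
#'
#' Keeps SNPs with p below `p_max` and gene distance below `max_dist`
#' whose gene is expressed AND differentially expressed or tissue
#' specific in at least one tissue; emits one row per (gene, SNP, trait).
#' The tissue column reports the tissue of strongest evidence - the DE
#' tissue with the smallest posterior null probability when the gene is
#' DE, otherwise the TS assigned tissue - and the fold change comes from
#' the DE call in that tissue (NA for TS-only genes).
#'
#' SNPs whose gene is outside the expression universe are dropped with a
#' logged count, not an error.
#'
#' @param snps SNP association table (see [read_snp_table()]).
#' @param expressed character vector: the expressed-gene universe.
#' @param de_calls data.frame with columns gene, tissue, d, fold_change,
#'   posterior_null, is_de (rows for all tissues analyzed).
#' @param ts_calls a `ts_result` (or data.frame with gene,
#'   assigned_tissue, is_ts).
#' @param p_max GWAS p-value ceiling (default 0.01).
#' @param max_dist distance ceiling in bp (default 10000).
#' @return data.frame of integrated loci (gene, de_flag, ts_flag, tissue,
#'   fold_change, snp, chrom, pos, trait, pvalue, distance_bp, side);
#'   attribute `n_dropped_unknown_gene` counts dropped SNPs.
#' @export
integrate_gwas <- function(snps, expressed, de_calls, ts_calls,
                           p_max = 0.01, max_dist = 10000) {
  snps <- validate_snp_table(snps)
  assert_scalar_number(p_max, "p_max", min = 0, max = 1)
  assert_scalar_number(max_dist, "max_dist", min = 0)
  empty <- data.frame(gene = character(0), de_flag = integer(0),
                      ts_flag = integer(0), tissue = character(0),
                      fold_change = numeric(0), snp = character(0),
                      chrom = character(0), pos = numeric(0),
                      trait = character(0), pvalue = numeric(0),
                      distance_bp = numeric(0), side = character(0))
  if (nrow(snps) == 0L) {
    attr(empty, "n_dropped_unknown_gene") <- 0L
    return(empty)
  }
  known <- snps$gene %in% expressed
  n_dropped <- sum(!known)
  snps <- snps[known & snps$pvalue < p_max & snps$distance_bp < max_dist, ,
               drop = FALSE]

  de_by_gene <- de_calls[de_calls$is_de, , drop = FALSE]
  ts_by_gene <- ts_calls[ts_calls$is_ts, , drop = FALSE]
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    g <- snps$gene[i]
    de_g <- de_by_gene[de_by_gene$gene == g, , drop = FALSE]
    ts_g <- ts_by_gene[ts_by_gene$gene == g, , drop = FALSE]
    de_flag <- as.integer(nrow(de_g) > 0)
    ts_flag <- as.integer(nrow(ts_g) > 0)
    if (de_flag + ts_flag == 0L) return(NULL)
    if (de_flag) {
      best <- de_g[which.min(de_g$posterior_null), , drop = FALSE]
      tissue <- best$tissue
      fold <- best$fold_change
    } else {
      tissue <- ts_g$assigned_tissue[1]
      fold <- NA_real_
    }
    data.frame(gene = g, de_flag = de_flag, ts_flag = ts_flag,
               tissue = tissue, fold_change = fold,
               snp = snps$snp[i], chrom = as.character(snps$chrom[i]),
               pos = snps$pos[i], trait = snps$trait[i],
               pvalue = snps$pvalue[i], distance_bp = snps$distance_bp[i],
               side = snps$side[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "n_dropped_unknown_gene") <- n_dropped
  out
}

#' Summarize integrated loci
#'
#' @param loci output of [integrate_gwas()] (or the packaged locus table
#'   via [example_loci()]).
#' @param uterine_tissues tissue labels counted as uterus/endometrium
#'   (default UTE and END).
#' @return list of counts: total, per_trait (named), within_gene
#'   (distance 0), uterus_endometrium, de_flagged, ts_flagged.
#' @export
summarize_loci <- function(loci, uterine_tissues = c("UTE", "END")) {
  per_trait <- stats::setNames(integer(length(TRAITS)), TRAITS)
  if (nrow(loci)) {
    tt <- table(factor(loci$trait, TRAITS))
    per_trait[names(tt)] <- as.integer(tt)
  }
  list(
    total = nrow(loci),
    per_trait = per_trait,
    within_gene = sum(loci$distance_bp == 0),
    uterus_endometrium = sum(loci$tissue %in% uterine_tissues),
    de_flagged = sum(loci$de_flag == 1),
    ts_flagged = sum(loci$ts_flag == 1)
  )
}

#' Packaged example locus table
#'
#' The 25-row integrated locus table bundled with the package: genes
#' harboring SNPs associated with the heifer fertility traits ACL, FSC
#' and HPG, with their DE/TS evidence, tissue, signed fold change and
#' SNP association details.
#'
#' @return data.frame in the [integrate_gwas()] output format.
#' @export
example_loci <- function() {
  path <- system.file("extdata", "heifer_fertility_loci.tsv",
                      package = "pubnet", mustWork = TRUE)
  loci <- read_tsv(path)
  loci$chrom <- as.character(loci$chrom)
  loci
}
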
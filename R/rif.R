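#' Regulator-target correlations per physiological state
#'
#' Pearson correlation of each regulator-target pair across the PRE
#' libraries (r1) and across the POST libraries (r2). Differential
#' wiring is dw = r1 - r2. Zero-variance profiles give correlation 0 and
#' are flagged.
#'
#' @param norm genes x libraries normalized matrix.
#' @param sheet sample sheet aligned to `norm`; each state needs >= 3
#'   libraries.
#' @param regulators,targets gene ids present in `norm`.
#' @return list with matrices `r1`, `r2` (regulators x targets), `dw`,
#'   and `zero_variance` (logical matrix flagging pairs involving a flat
#'   profile).
#' @export
state_correlations <- function(norm, sheet, regulators, targets) {
  sheet <- align_sheet(sheet, norm)
  miss <- setdiff(c(regulators, targets), rownames(norm))
  if (length(miss)) stop2("genes absent from matrix: ",
                          paste(miss, collapse = ", "))
  cor_state <- function(state) {
    sel <- sheet$state == state
    if (sum(sel) < 3L) stop2("fewer than 3 libraries in state ", state)
    X <- t(norm[regulators, sel, drop = FALSE])
    Y <- t(norm[targets, sel, drop = FALSE])
    flat_x <- apply(X, 2L, stats::sd) == 0
    flat_y <- apply(Y, 2L, stats::sd) == 0
    r <- suppressWarnings(stats::cor(X, Y))
    flag <- outer(flat_x, flat_y, "|")
    r[!is.finite(r)] <- 0
    list(r = r, flag = flag)
  }
  pre <- cor_state("PRE")
  post <- cor_state("POST")
  list(r1 = pre$r, r2 = post$r, dw = pre$r - post$r,
       zero_variance = pre$flag | post$flag)
}

#' Regulatory impact factors
#'
#' For regulator r against the n_DETS target genes (the union of DE and
#' TS genes), with a_j the target's average expression over all samples,
#' d_j its differential expression, e1_j/e2_j its average expression in
#' PRE/POST, and r1_rj/r2_rj the state co-expression correlations
#' (dw_rj = r1_rj - r2_rj):
#' \deqn{RIF1_r = \frac{1}{n_{DETS}} \sum_j a_j d_j dw_{rj}^2}
#' \deqn{RIF2_r = \frac{1}{n_{DETS}} \sum_j (e1_j r1_{rj})^2 -
#'   (e2_j r2_{rj})^2}
#' Raw scores are z-standardized across regulators; |z| >= `z_cut` flags
#' a regulator significant (1.96 for nominal 5%). Self-pairs (a regulator
#' that is also a target) are excluded from its own sums.
#'
#' @param r1,r2 regulators x targets correlation matrices.
#' @param a,d,e1,e2 per-target vectors aligned to the columns of `r1`.
#' @param z_cut significance cutoff on |z| (default 1.96).
#' @return object of class `rif_result`: data.frame (regulator, rif1_raw,
#'   rif1_z, rif2_raw, rif2_z, significant) with the dw matrix attached
#'   as an attribute.
#' @export
rif_scores <- function(r1, r2, a, d, e1, e2, z_cut = 1.96) {
  if (!all(dim(r1) == dim(r2))) stop2("r1 and r2 must have equal dimensions")
  n_dets <- ncol(r1)
  if (is.null(n_dets) || n_dets < 1L) stop2("no DE/TS target genes")
  for (v in list(a, d, e1, e2)) {
    if (length(v) != n_dets) stop2("a, d, e1, e2 must match ncol(r1)")
  }
  dw <- r1 - r2
  regs <- rownames(r1)
  tgts <- colnames(r1)
  # Exclude self-pairs from the sums without changing n_DETS semantics:
  # a regulator contributes nothing to its own score.
  W1 <- dw^2
  T1 <- sweep(W1, 2L, a * d, "*")
  T2 <- sweep(r1^2, 2L, e1^2, "*") - sweep(r2^2, 2L, e2^2, "*")
  if (!is.null(regs) && !is.null(tgts)) {
    self <- outer(regs, tgts, "==")
    T1[self] <- 0
    T2[self] <- 0
  }
  rif1 <- rowSums(T1) / n_dets
  rif2 <- rowSums(T2) / n_dets
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  res <- data.frame(
    regulator = regs %||% as.character(seq_len(nrow(r1))),
    rif1_raw = rif1, rif1_z = zs(rif1),
    rif2_raw = rif2, rif2_z = zs(rif2)
  )
  res$significant <- abs(res$rif1_z) >= z_cut | abs(res$rif2_z) >= z_cut
  rownames(res) <- NULL
  class(res) <- c("rif_result", "data.frame")
  attr(res, "dw") <- dw
  res
}

#' Nine-criteria transcription-factor ranking
#'
#' Ranks candidate regulators by nine criteria: RIF1, RIF2, overall DE,
#' maximum DE, connections in the PRE network, connections in the POST
#' network, fold change in connections, and network expansion ability in
#' PRE and in POST. Each criterion is ranked descending by |value|; the
#' aggregate is the mean rank, with ties broken by the RIF1 rank and then
#' regulator id. The ranking is invariant to input row order.
#'
#' @param criteria data.frame with column `regulator` plus the nine
#'   criterion columns `rif1`, `rif2`, `de_overall`, `de_max`,
#'   `conn_pre`, `conn_post`, `conn_fold`, `expand_pre`, `expand_post`.
#' @return data.frame sorted by aggregate rank, with per-criterion rank
#'   columns (`rank_<criterion>`) and `aggregate_rank`.
#' @export
rank_regulators <- function(criteria) {
  needed <- c("rif1", "rif2", "de_overall", "de_max", "conn_pre",
              "conn_post", "conn_fold", "expand_pre", "expand_post")
  miss <- setdiff(c("regulator", needed), names(criteria))
  if (length(miss)) stop2("missing criterion column(s): ",
                          paste(miss, collapse = ", "))
  criteria <- criteria[order(criteria$regulator), , drop = FALSE]
  ranks <- vapply(needed, function(cn) {
    rank(-abs(criteria[[cn]]), ties.method = "average")
  }, numeric(nrow(criteria)))
  out <- criteria
  colnames(ranks) <- paste0("rank_", needed)
  out <- cbind(out, ranks)
  out$aggregate_rank <- rowMeans(ranks)
  out <- out[order(out$aggregate_rank, out$rank_rif1, out$regulator), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full RIF analysis from normalized and log expression
#'
#' Convenience wrapper: computes the state correlations on the normalized
#' matrix and the expression weights (a_j, e1_j, e2_j) on the log2 RPKM
#' abundance scale (weights must reflect expression level, which the
#' mean-centered normalized solutions do not), d_j as the mean of the
#' per-tissue DE measures, then scores regulators.
#'
#' @param norm normalized matrix; `logmat` log2 RPKM matrix (same
#'   libraries).
#' @param sheet sample sheet.
#' @param regulators candidate regulator ids.
#' @param targets DE-or-TS target gene ids.
#' @return a `rif_result` (see [rif_scores()]).
#' @export
rif_analysis <- function(norm, logmat, sheet, regulators, targets) {
  sheet <- align_sheet(sheet, norm)
  targets <- setdiff(targets, character(0))
  sc <- state_correlations(norm, sheet, regulators, targets)
  tiss <- unique(sheet$tissue)
  dmat <- vapply(tiss, function(tt) de_measure(norm, sheet, tt),
                 numeric(nrow(norm)))
  d <- rowMeans(dmat)[targets]
  a <- rowMeans(logmat[targets, , drop = FALSE])
  e1 <- rowMeans(logmat[targets, sheet$state == "PRE", drop = FALSE])
  e2 <- rowMeans(logmat[targets, sheet$state == "POST", drop = FALSE])
  rif_scores(sc$r1, sc$r2, a = a, d = d, e1 = e1, e2 = e2)
}
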
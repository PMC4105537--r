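#' First-order partial correlation
#'
#' Correlation between x and y once the influence of z is removed:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#'
#' @param rxy,rxz,ryz pairwise correlations in [-1, 1].
#' @return the partial correlation; error when |rxz| or |ryz| equals 1
#'   (the partial is undefined; such a neighbor is maximally
#'   informative).
#' @export
partial_correlation <- function(rxy, rxz, ryz) {
  vals <- c(rxy, rxz, ryz)
  if (any(!is.finite(vals)) || any(abs(vals) > 1 + 1e-12)) {
    stop2("correlations must be finite values in [-1, 1]")
  }
  if (abs(abs(rxz) - 1) < 1e-12 || abs(abs(ryz) - 1) < 1e-12) {
    stop2("partial correlation undefined: a conditioning correlation is +/-1")
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' PCIT significance filter for a correlation matrix
#'
#' Partial-correlation-and-information-theory soft thresholding. For
#' every gene trio (x, y, z) the three first-order partial correlations
#' are computed and averaged against their direct correlations into a
#' local tolerance
#' \deqn{\epsilon_{xyz} = \frac{1}{3}\left(\frac{r_{xy.z}}{r_{xy}} +
#'   \frac{r_{xz.y}}{r_{xz}} + \frac{r_{yz.x}}{r_{yz}}\right)}
#' (terms with zero denominator are dropped from the average; a trio
#' whose three terms are all undefined eliminates nothing). The x-y
#' association is flagged non-significant if some third gene z satisfies
#' both |r_xy| < |eps * r_xz| and |r_xy| < |eps * r_yz|. Surviving pairs
#' with nonzero correlation are the significant edges. The result is
#' independent of gene ordering.
#'
#' The implementation loops over the conditioning gene z with vectorized
#' n x n operations; a naive O(n^3) triple loop over trios is the
#' normative reference and the two are tested for equality.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @return logical matrix of the same shape: TRUE where the pair is a
#'   significant edge (diagonal FALSE).
#' @export
pcit <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop2("corr must be a square matrix")
  }
  if (max(abs(corr - t(corr))) > 1e-8) stop2("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop2("corr must have unit diagonal")
  n <- nrow(corr)
  keep <- matrix(TRUE, n, n)
  if (n >= 3L) {
    for (z in seq_len(n)) {
      rz <- corr[, z]
      # partials given each of the trio members, vectorized over (x, y)
      den_z <- sqrt(pmax(1 - rz^2, 0))
      pz <- (corr - tcrossprod(rz)) / tcrossprod(den_z)    # r_xy.z
      rxy <- corr
      rxz <- matrix(rz, n, n)                               # column x -> r_xz
      ryz <- t(rxz)                                         # r_yz
      den_y <- sqrt(pmax((1 - rxy^2) * (1 - ryz^2), 0))
      py <- (rxz - rxy * ryz) / den_y                       # r_xz.y
      den_x <- sqrt(pmax((1 - rxy^2) * (1 - rxz^2), 0))
      px <- (ryz - rxy * rxz) / den_x                       # r_yz.x
      t1 <- pz / rxy
      t2 <- py / rxz
      t3 <- px / ryz
      ok1 <- is.finite(t1); ok2 <- is.finite(t2); ok3 <- is.finite(t3)
      cnt <- ok1 + ok2 + ok3
      ssum <- ifelse(ok1, t1, 0) + ifelse(ok2, t2, 0) + ifelse(ok3, t3, 0)
      eps <- ssum / cnt                                     # NaN when cnt == 0
      elim <- abs(rxy) < abs(eps * rxz) & abs(rxy) < abs(eps * ryz)
      elim[!is.finite(eps)] <- FALSE
      elim[, z] <- FALSE
      elim[z, ] <- FALSE
      diag(elim) <- FALSE
      keep <- keep & !elim
    }
  }
  keep <- keep & abs(corr) > 0
  diag(keep) <- FALSE
  dimnames(keep) <- dimnames(corr)
  keep
}

#' Build a co-expression network for one physiological state
#'
#' Pearson correlations across all the state's libraries (animals x
#' tissues; with animals nested in state this is the only reading giving
#' n >= 3 observations), filtered by [pcit()]. Node attributes carry the
#' tissue of maximum mean RPKM, a transcription-factor flag and the mean
#' expression in the state.
#'
#' @param norm genes x libraries normalized matrix.
#' @param sheet sample sheet aligned to `norm`.
#' @param genes gene ids to include (error if absent from `norm`).
#' @param state "PRE" or "POST".
#' @param rpkm optional RPKM matrix for tissue-of-maximum-expression
#'   attribution (defaults to `norm`).
#' @param tf_ids optional transcription-factor id list.
#' @return object of class `state_network`: list with `state`, `nodes`
#'   (data.frame gene, tissue_of_max_expression, is_TF, mean_expr,
#'   connectivity), `edges` (data.frame gene_a, gene_b, r) of significant
#'   edges only.
#' @export
build_state_network <- function(norm, sheet, genes, state,
                                rpkm = NULL, tf_ids = character(0)) {
  if (!state %in% STATES) stop2("state must be PRE or POST")
  sheet <- align_sheet(sheet, norm)
  miss <- setdiff(genes, rownames(norm))
  if (length(miss)) stop2("genes absent from matrix: ",
                          paste(miss, collapse = ", "))
  genes <- sort(unique(genes))
  sel <- sheet$state == state
  if (sum(sel) < 3L) stop2("fewer than 3 libraries in state ", state)
  X <- t(norm[genes, sel, drop = FALSE])
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  mask <- pcit(r)
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      r = r[idx])
  conn <- stats::setNames(integer(length(genes)), genes)
  tab <- table(c(edges$gene_a, edges$gene_b))
  conn[names(tab)] <- as.integer(tab)
  attrib <- if (is.null(rpkm)) norm else rpkm
  prof <- t(rowsum(t(attrib[genes, , drop = FALSE]),
                   group = factor(sheet$tissue)))
  cnts <- as.vector(table(factor(sheet$tissue)))
  prof <- sweep(prof, 2L, cnts, "/")
  nodes <- data.frame(
    gene = genes,
    tissue_of_max_expression = colnames(prof)[max.col(prof,
                                                      ties.method = "first")],
    is_TF = genes %in% tf_ids,
    mean_expr = rowMeans(norm[genes, sel, drop = FALSE]),
    connectivity = as.integer(conn)
  )
  rownames(nodes) <- NULL
  structure(list(state = state, nodes = nodes, edges = edges),
            class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat(sprintf("%s-state co-expression network: %d nodes, %d significant edges\n",
              x$state, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hub genes of a network
#'
#' Nodes whose significant-edge connectivity exceeds the mean by more
#' than two standard deviations (nominal P < 0.01).
#'
#' @param net a `state_network`.
#' @param n_sd threshold in standard deviations (default 2).
#' @return character vector of hub gene ids.
#' @export
find_hubs <- function(net, n_sd = 2) {
  if (!inherits(net, "state_network")) stop2("net must be a state_network")
  k <- net$nodes$connectivity
  if (length(k) < 2L) stop2("need >= 2 nodes")
  s <- stats::sd(k)
  if (s == 0) return(character(0))
  net$nodes$gene[k > mean(k) + n_sd * s]
}

#' Write a network edge list in SIF format
#'
#' One line per significant edge, `geneA pp geneB`, for network viewers.
#'
#' @param net a `state_network`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_sif <- function(net, path) {
  lines <- sprintf("%s pp %s", net$edges$gene_a, net$edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}
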
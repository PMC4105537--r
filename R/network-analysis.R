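#' Compare PRE and POST networks
#'
#' Set algebra on significant edges: persistent (both states),
#' disappeared (PRE only) and emerged (POST only). Tissue attribution is
#' by edge endpoints: each edge contributes one count to the
#' tissue_of_max_expression of each of its two nodes, and per-tissue
#' percentages are normalized by total endpoint counts so each column
#' sums to 100. Per-node connection fold change is
#' log2((POST + 1) / (PRE + 1)).
#'
#' @param pre,post `state_network` objects over the same node universe.
#' @return object of class `network_delta`: edge-set data.frames
#'   `persistent`, `disappeared`, `emerged`; `tissue_pct` (tissue,
#'   pct_pre, pct_post, pct_disappear, pct_emerge); `node_fold`
#'   (gene, conn_pre, conn_post, log2_fold).
#' @export
compare_networks <- function(pre, post) {
  if (!inherits(pre, "state_network") || !inherits(post, "state_network")) {
    stop2("pre and post must be state_network objects")
  }
  sym_diff <- c(setdiff(pre$nodes$gene, post$nodes$gene),
                setdiff(post$nodes$gene, pre$nodes$gene))
  if (length(sym_diff)) {
    stop2("differing node sets: ", paste(sym_diff, collapse = ", "))
  }
  key_pre <- edge_key(pre$edges$gene_a, pre$edges$gene_b)
  key_post <- edge_key(post$edges$gene_a, post$edges$gene_b)
  persistent <- pre$edges[key_pre %in% key_post, , drop = FALSE]
  disappeared <- pre$edges[!key_pre %in% key_post, , drop = FALSE]
  emerged <- post$edges[!key_post %in% key_pre, , drop = FALSE]

  tissue_of <- stats::setNames(pre$nodes$tissue_of_max_expression,
                               pre$nodes$gene)
  tissues <- sort(unique(tissue_of))
  pct <- function(edges) {
    if (nrow(edges) == 0L) return(stats::setNames(rep(NA_real_,
                                                      length(tissues)),
                                                  tissues))
    ends <- factor(tissue_of[c(edges$gene_a, edges$gene_b)], tissues)
    100 * as.vector(table(ends)) / length(ends)
  }
  tissue_pct <- data.frame(
    tissue = tissues,
    pct_pre = pct(pre$edges),
    pct_post = pct(post$edges),
    pct_disappear = pct(disappeared),
    pct_emerge = pct(emerged)
  )
  rownames(tissue_pct) <- NULL

  conn_pre <- stats::setNames(pre$nodes$connectivity, pre$nodes$gene)
  conn_post <- stats::setNames(post$nodes$connectivity, post$nodes$gene)
  genes <- sort(pre$nodes$gene)
  node_fold <- data.frame(
    gene = genes,
    conn_pre = as.integer(conn_pre[genes]),
    conn_post = as.integer(conn_post[genes]),
    log2_fold = log2((conn_post[genes] + 1) / (conn_pre[genes] + 1))
  )
  rownames(node_fold) <- NULL
  structure(list(persistent = persistent, disappeared = disappeared,
                 emerged = emerged, tissue_pct = tissue_pct,
                 node_fold = node_fold),
            class = "network_delta")
}

#' Number of unordered transcription-factor trios
#'
#' @param n_tf number of TFs (>= 3).
#' @return n_tf * (n_tf - 1) * (n_tf - 2) / 6 (binomial coefficient
#'   C(n_tf, 3)), e.g. 7,971,964 trios for 364 TFs.
#' @export
trio_count <- function(n_tf) {
  n_tf <- assert_count(n_tf, "n_tf", min = 3L)
  n_tf * (n_tf - 1) * (n_tf - 2) / 6
}

# Neighbor incidence of TFs in a network: TFs x nodes logical matrix.
.tf_neighbors <- function(net, tf_ids) {
  nodes <- net$nodes$gene
  nb <- matrix(FALSE, length(tf_ids), length(nodes),
               dimnames = list(tf_ids, nodes))
  ea <- net$edges$gene_a
  eb <- net$edges$gene_b
  for (i in seq_along(tf_ids)) {
    tf <- tf_ids[i]
    nb[i, c(eb[ea == tf], ea[eb == tf])] <- TRUE
  }
  nb
}

#' Exhaustive best-trio search over transcription factors
#'
#' Enumerates all C(n, 3) TF trios and selects the one whose combined
#' network neighborhoods cover the most nodes ("span most of the network
#' topology"); coverage ties are broken by minimal redundancy (the sum
#' of pairwise neighbor-set intersections), then by lexicographic trio
#' id — an information-lossless search in the sense that no trio is
#' skipped.
#'
#' @param net a `state_network`.
#' @param tf_ids TF ids; at least 3 must be nodes of the network.
#' @return list with `trio` (3 ids), `coverage`, `redundancy`,
#'   `n_trios_examined`.
#' @export
best_trio <- function(net, tf_ids) {
  tf_ids <- sort(intersect(unique(tf_ids), net$nodes$gene))
  if (length(tf_ids) < 3L) stop2("need >= 3 TFs present in the network")
  nb <- .tf_neighbors(net, tf_ids)
  combs <- utils::combn(length(tf_ids), 3L)
  inter <- tcrossprod(nb * 1)      # pairwise |intersection|
  best <- NULL
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]; k <- combs[3, c]
    cov <- sum(nb[i, ] | nb[j, ] | nb[k, ])
    red <- inter[i, j] + inter[i, k] + inter[j, k]
    if (is.null(best) || cov > best$coverage ||
        (cov == best$coverage && red < best$redundancy)) {
      best <- list(trio = tf_ids[c(i, j, k)], coverage = cov,
                   redundancy = red)
    }
  }
  best$n_trios_examined <- ncol(combs)
  best
}

#' Network expansion ability of each transcription factor
#'
#' The node's neighbor-union coverage when paired with its two best
#' partners, i.e. the maximal trio coverage over trios containing the
#' node.
#'
#' @param net a `state_network`.
#' @param tf_ids TF ids (>= 3 present in the network).
#' @return named numeric vector of coverages (0 for TFs absent from the
#'   network).
#' @export
tf_expansion_ability <- function(net, tf_ids) {
  tf_ids <- sort(unique(tf_ids))
  present <- intersect(tf_ids, net$nodes$gene)
  out <- stats::setNames(rep(0, length(tf_ids)), tf_ids)
  if (length(present) < 3L) return(out)
  nb <- .tf_neighbors(net, present)
  np <- length(present)
  pairs <- utils::combn(np, 2L)
  for (i in seq_len(np)) {
    best <- 0
    op <- pairs[, pairs[1, ] != i & pairs[2, ] != i, drop = FALSE]
    for (c in seq_len(ncol(op))) {
      cov <- sum(nb[i, ] | nb[op[1, c], ] | nb[op[2, c], ])
      if (cov > best) best <- cov
    }
    out[present[i]] <- best
  }
  out
}

#' Extract the DE-plus-TF subnetwork for selected tissues
#'
#' Induced subgraph on the genes DE in the named tissues plus the TFs
#' connected to at least one of them. Node attributes include a
#' connectivity tier (low/medium/high terciles of the subnetwork
#' connectivity).
#'
#' @param net a `state_network`.
#' @param de_calls data.frame with columns gene, tissue, is_de (as
#'   produced by the pipeline's DE stage).
#' @param tissues tissues whose DE genes seed the subnetwork (default
#'   hypothalamus and pituitary, `c("HYP", "PIT")`).
#' @param tf_ids TF ids.
#' @return a `state_network` whose nodes carry `tier`; edges are a
#'   subset of the parent's.
#' @export
extract_subnetwork <- function(net, de_calls, tissues = c("HYP", "PIT"),
                               tf_ids = character(0)) {
  if (nrow(de_calls) > 0L) {
    bad <- setdiff(tissues, unique(de_calls$tissue))
    if (length(bad)) stop2("unknown tissue name(s): ",
                           paste(bad, collapse = ", "))
  }
  de_genes <- unique(de_calls$gene[de_calls$is_de &
                                     de_calls$tissue %in% tissues])
  de_genes <- intersect(de_genes, net$nodes$gene)
  ea <- net$edges$gene_a
  eb <- net$edges$gene_b
  tf_conn <- unique(c(ea[eb %in% de_genes], eb[ea %in% de_genes]))
  tf_conn <- intersect(tf_conn, tf_ids)
  keep <- sort(unique(c(de_genes, tf_conn)))
  sel <- ea %in% keep & eb %in% keep
  edges <- net$edges[sel, , drop = FALSE]
  nodes <- net$nodes[net$nodes$gene %in% keep, , drop = FALSE]
  conn <- stats::setNames(integer(nrow(nodes)), nodes$gene)
  tab <- table(c(edges$gene_a, edges$gene_b))
  conn[names(tab)] <- as.integer(tab)
  nodes$connectivity <- as.integer(conn[nodes$gene])
  if (nrow(nodes)) {
    qs <- stats::quantile(nodes$connectivity, c(1 / 3, 2 / 3))
    nodes$tier <- cut(nodes$connectivity,
                      breaks = c(-Inf, qs[1], qs[2], Inf),
                      labels = c("low", "medium", "high"))
  } else {
    nodes$tier <- factor(character(0), c("low", "medium", "high"))
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(state = net$state, nodes = nodes, edges = edges),
            class = "state_network")
}
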
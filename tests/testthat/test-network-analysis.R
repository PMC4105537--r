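test_that("network comparison set algebra", {
  e_ab <- data.frame(gene_a = "a", gene_b = "b", r = 0.9)
  e_bc <- data.frame(gene_a = "b", gene_b = "c", r = 0.8)
  nodes <- c("a", "b", "c")
  pre <- toy_network(e_ab, nodes, state = "PRE")
  post <- toy_network(e_bc, nodes, state = "POST")
  d <- compare_networks(pre, post)
  expect_equal(nrow(d$persistent), 0L)
  expect_equal(edge_key(d$disappeared$gene_a, d$disappeared$gene_b), "a|b")
  expect_equal(edge_key(d$emerged$gene_a, d$emerged$gene_b), "b|c")

  same <- compare_networks(pre, toy_network(e_ab, nodes, state = "POST"))
  expect_equal(nrow(same$disappeared), 0L)
  expect_equal(nrow(same$emerged), 0L)
  expect_equal(nrow(same$persistent), 1L)

  expect_error(compare_networks(pre, toy_network(e_bc, c(nodes, "d"))),
               "differing node sets")
})

test_that("set identities hold on random network pairs", {
  set.seed(40)
  nodes <- sprintf("n%03d", 1:100)
  rand_net <- function(state) {
    idx <- which(upper.tri(diag(100)), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 300), ]
    toy_network(data.frame(gene_a = nodes[pick[, 1]],
                           gene_b = nodes[pick[, 2]],
                           r = stats::runif(300, -1, 1)),
                nodes, state = state)
  }
  pre <- rand_net("PRE"); post <- rand_net("POST")
  d <- compare_networks(pre, post)
  expect_equal(nrow(d$persistent) + nrow(d$disappeared), nrow(pre$edges))
  expect_equal(nrow(d$persistent) + nrow(d$emerged), nrow(post$edges))
  # endpoint-attributed percentages sum to 100 per column
  for (col in c("pct_pre", "pct_post", "pct_disappear", "pct_emerge")) {
    expect_equal(sum(d$tissue_pct[[col]]), 100, tolerance = 0.1)
  }
})

test_that("trio_count closed form agrees with explicit enumeration", {
  expect_equal(trio_count(3), 1)
  expect_equal(trio_count(10), 120)
  expect_equal(trio_count(364), 7971964)
  for (n in c(5, 12, 23, 30)) {
    expect_equal(trio_count(n), ncol(utils::combn(n, 3)))
  }
  expect_error(trio_count(2), "n_tf")
})

test_that("best trio maximizes coverage with redundancy tie-break", {
  # hand-built neighbor sets over 6 TFs
  nb <- list(T1 = c("x1", "x2", "x3"), T2 = c("x3", "x4"),
             T3 = c("x5", "x6", "x7", "x8"), T4 = character(0),
             T5 = c("x1", "x2", "x3"),      # duplicate of T1
             T6 = c("x9", "x10"))
  edges <- do.call(rbind, lapply(names(nb), function(tf) {
    if (!length(nb[[tf]])) return(NULL)
    data.frame(gene_a = tf, gene_b = nb[[tf]], r = 0.9)
  }))
  net <- toy_network(edges,
                     nodes = sort(unique(c(names(nb), unlist(nb)))),
                     tf_ids = names(nb))
  got <- best_trio(net, names(nb))
  want <- naive_best_trio(lapply(nb, function(x) x))
  expect_equal(got$trio, sort(want$trio))
  expect_equal(got$coverage, want$coverage)
  expect_equal(got$n_trios_examined, choose(6, 3))
  # the empty TF is never chosen, and the duplicate pair is avoided
  expect_false("T4" %in% got$trio)
  expect_false(all(c("T1", "T5") %in% got$trio))
  expect_error(best_trio(net, c("T1", "T2")), ">= 3")
})

test_that("expansion ability dominates any single neighborhood", {
  gen <- generate_dataset(sim_config(n_genes = 80, n_de = 15, n_ts = 15,
                                     seed = 19))
  logm <- log_transform(gen$matrix)
  fit <- fit_mixed_model(logm, gen$sheet)
  norm <- normalize_expression(fit, gen$sheet, allow_unconverged = TRUE)
  genes <- rownames(norm)[1:40]
  net <- build_state_network(norm, gen$sheet, genes, "PRE")
  tfs <- genes[1:6]
  exp_ab <- tf_expansion_ability(net, tfs)
  bt <- best_trio(net, tfs)
  expect_equal(max(exp_ab), bt$coverage)
  for (tf in tfs) {
    own <- sum(net$edges$gene_a == tf | net$edges$gene_b == tf)
    expect_gte(exp_ab[tf], own)
  }
})

test_that("subnetwork extraction audits membership", {
  edges <- data.frame(
    gene_a = c("de1", "de1", "tf1", "tf2", "oth1"),
    gene_b = c("de2", "tf1", "oth1", "oth2", "oth2"),
    r = c(0.9, 0.8, 0.7, 0.6, 0.5))
  net <- toy_network(edges, tf_ids = c("tf1", "tf2"))
  de_calls <- data.frame(gene = c("de1", "de2", "oth1"),
                         tissue = c("HYP", "HYP", "LIV"),
                         is_de = c(TRUE, TRUE, TRUE))
  sub <- extract_subnetwork(net, de_calls, tissues = "HYP",
                            tf_ids = c("tf1", "tf2"))
  expect_setequal(sub$nodes$gene, c("de1", "de2", "tf1"))
  # induced edges are a subset of the parent's
  expect_true(all(edge_key(sub$edges$gene_a, sub$edges$gene_b) %in%
                    edge_key(net$edges$gene_a, net$edges$gene_b)))
  # every node is DE-in-tissue or a TF with an edge to one
  for (g in sub$nodes$gene) {
    is_de <- g %in% de_calls$gene[de_calls$is_de & de_calls$tissue == "HYP"]
    is_tf <- g %in% c("tf1", "tf2")
    expect_true(is_de || is_tf)
  }
  expect_equal(levels(sub$nodes$tier), c("low", "medium", "high"))

  none <- extract_subnetwork(net, de_calls[0, ], tissues = "HYP")
  expect_equal(nrow(none$nodes), 0L)
  expect_error(extract_subnetwork(net, de_calls, tissues = "SPLEEN"),
               "SPLEEN")
})
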
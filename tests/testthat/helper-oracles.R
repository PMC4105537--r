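# Independent oracle implementations and small fixture builders shared
# across the test files. Oracles are deliberately naive (dense solves,
# triple loops, explicit enumeration) and independent of the package's
# optimized code paths.

# Small simulated data set with the default eight-tissue design.
small_dataset <- function(n_genes = 120, seed = 42, ...) {
  generate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Dense Henderson mixed-model-equation solve for the gene-factor model,
# at fixed variance components. Returns the fixed library solutions and
# the random-effect BLUPs.
dense_mme <- function(logmat, sheet, s2) {
  m <- nrow(logmat); n <- ncol(logmat)
  genes <- rownames(logmat); libs <- colnames(logmat)
  tiss <- sort(unique(sheet$tissue)); anim <- sort(unique(sheet$animal))
  stat <- intersect(c("PRE", "POST"), unique(sheet$state))
  y <- as.vector(t(logmat))              # obs ordered gene-major
  gene_i <- rep(seq_len(m), each = n)
  lib_i <- rep(seq_len(n), m)
  t_i <- match(sheet$tissue, tiss)[lib_i]
  a_i <- match(sheet$animal, anim)[lib_i]
  p_i <- match(sheet$state, stat)[lib_i]
  ind <- function(idx, k) {
    M <- matrix(0, length(idx), k); M[cbind(seq_along(idx), idx)] <- 1; M
  }
  X <- ind(lib_i, n)
  Zg <- ind(gene_i, m)
  Zgt <- ind((gene_i - 1L) * length(tiss) + t_i, m * length(tiss))
  Zga <- ind((gene_i - 1L) * length(anim) + a_i, m * length(anim))
  Zgp <- ind((gene_i - 1L) * length(stat) + p_i, m * length(stat))
  Z <- cbind(Zg, Zgt, Zga, Zgp)
  dinv <- c(rep(1 / s2[1], m), rep(1 / s2[2], m * length(tiss)),
            rep(1 / s2[3], m * length(anim)), rep(1 / s2[4], m * length(stat)))
  se <- s2[5]
  lhs <- rbind(cbind(crossprod(X) / se, crossprod(X, Z) / se),
               cbind(crossprod(Z, X) / se,
                     crossprod(Z) / se + diag(dinv)))
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / se
  sol <- solve(lhs, rhs)
  b <- sol[seq_len(n)]
  u <- sol[-seq_len(n)]
  list(
    library = stats::setNames(b, libs),
    G = stats::setNames(u[seq_len(m)], genes),
    GT = matrix(u[m + seq_len(m * length(tiss))], m, length(tiss),
                byrow = TRUE, dimnames = list(genes, tiss)),
    GA = matrix(u[m + m * length(tiss) + seq_len(m * length(anim))], m,
                length(anim), byrow = TRUE, dimnames = list(genes, anim)),
    GP = matrix(u[m + m * (length(tiss) + length(anim)) +
                    seq_len(m * length(stat))], m, length(stat),
                byrow = TRUE, dimnames = list(genes, stat))
  )
}

# Naive O(n^3) PCIT reference: the normative definition.
naive_pcit <- function(corr) {
  n <- nrow(corr)
  keep <- abs(corr) > 0
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  for (x in seq_len(n - 1)) for (y in (x + 1):n) {
    rxy <- corr[x, y]
    for (z in setdiff(seq_len(n), c(x, y))) {
      rxz <- corr[x, z]; ryz <- corr[y, z]
      p1 <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      p2 <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      p3 <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      ts <- c(p1 / rxy, p2 / rxz, p3 / ryz)
      ts <- ts[is.finite(ts)]
      if (!length(ts)) next
      eps <- mean(ts)
      if (abs(rxy) < abs(eps * rxz) && abs(rxy) < abs(eps * ryz)) {
        keep[x, y] <- keep[y, x] <- FALSE
        break
      }
    }
  }
  keep
}

# Brute-force trio scoring from explicit neighbor sets.
naive_best_trio <- function(neighbors) {
  ids <- sort(names(neighbors))
  best <- NULL
  cmb <- utils::combn(ids, 3L)
  for (c in seq_len(ncol(cmb))) {
    tr <- cmb[, c]
    cov <- length(unique(unlist(neighbors[tr])))
    red <- length(intersect(neighbors[[tr[1]]], neighbors[[tr[2]]])) +
      length(intersect(neighbors[[tr[1]]], neighbors[[tr[3]]])) +
      length(intersect(neighbors[[tr[2]]], neighbors[[tr[3]]]))
    if (is.null(best) || cov > best$coverage ||
        (cov == best$coverage && red < best$redundancy)) {
      best <- list(trio = tr, coverage = cov, redundancy = red)
    }
  }
  best
}

# Hand-built state_network from an edge list.
toy_network <- function(edges, nodes = NULL, state = "PRE",
                        tf_ids = character(0)) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  conn <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(c(edges$gene_a, edges$gene_b))
  conn[names(tab)] <- as.integer(tab)
  structure(list(
    state = state,
    nodes = data.frame(gene = nodes,
                       tissue_of_max_expression = rep("HYP", length(nodes)),
                       is_TF = nodes %in% tf_ids,
                       mean_expr = 0,
                       connectivity = as.integer(conn)),
    edges = edges
  ), class = "state_network")
}
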
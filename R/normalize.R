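#' Fit the gene-factor mixed model to log2 expression by EM-REML
#'
#' Fits
#' \deqn{Y_{ijtkp} = \mu + L_i + G_j + GT_{jt} + GA_{jk} + GP_{jp} + e_{ijtkp}}
#' with library (\eqn{\mu + L_i}) fixed and the gene, gene x tissue,
#' gene x animal and gene x state terms random, mutually independent with
#' variances \eqn{\sigma^2_G, \sigma^2_{GT}, \sigma^2_{GA}, \sigma^2_{GP}}
#' and residual \eqn{\sigma^2_e}.
#'
#' Because every gene is observed in every library, conditioning on the
#' library effects makes the equations decouple by gene: all genes share
#' one library-by-library covariance
#' \eqn{V = \sigma^2_G J + \sigma^2_{GT} C_T + \sigma^2_{GA} C_A +
#' \sigma^2_{GP} C_P + \sigma^2_e I}
#' (C's are same-level indicator matrices), the GLS library-effect
#' estimate is the per-library mean over genes, and EM-REML updates and
#' BLUP solutions use only n x n dense algebra. This is an implementation
#' contract, not an approximation: on small instances the solutions equal
#' a dense Henderson mixed-model-equation solve with the same components.
#'
#' Initialization splits the total phenotypic variance equally across the
#' five components. The restricted log-likelihood is non-decreasing over
#' EM iterations; convergence is declared when every component's relative
#' change falls below `tol`.
#'
#' @param logmat genes x libraries matrix of log2 expression.
#' @param sheet sample sheet aligned to `logmat`.
#' @param tol relative convergence tolerance on components (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).
#' @return object of class `mm_fit`: mu, library_effects, gene_solutions,
#'   gene_tissue_solutions, gene_animal_solutions, gene_state_solutions,
#'   variance_components, loglik (trace), n_reml_iterations, converged.
#' @export
fit_mixed_model <- function(logmat, sheet, tol = 1e-6, max_iter = 1000L) {
  if (!is.matrix(logmat) || nrow(logmat) < 2L || ncol(logmat) < 2L) {
    stop2("need a matrix with >= 2 genes and >= 2 libraries")
  }
  if (any(!is.finite(logmat))) stop2("log matrix has non-finite values")
  sheet <- align_sheet(sheet, logmat)
  tiss <- sort(unique(sheet$tissue))
  stat <- intersect(STATES, unique(sheet$state))
  cells <- table(factor(sheet$tissue, tiss), factor(sheet$state, stat))
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)
    stop2("empty (tissue, state) cell: ",
          paste(tiss[bad[, 1]], stat[bad[, 2]], sep = "/", collapse = ", "))
  }
  m <- nrow(logmat)
  n <- ncol(logmat)
  anim <- sort(unique(sheet$animal))

  Zt <- outer(sheet$tissue, tiss, "==") * 1
  Za <- outer(sheet$animal, anim, "==") * 1
  Zp <- outer(sheet$state, stat, "==") * 1
  Ct <- tcrossprod(Zt); Ca <- tcrossprod(Za); Cp <- tcrossprod(Zp)
  J <- matrix(1, n, n); I <- diag(n)

  ybar <- colMeans(logmat)
  R <- sweep(logmat, 2L, ybar)
  mu <- mean(ybar)

  empty_fit <- function(s2, conv, ll, it) {
    structure(list(
      mu = mu, library_effects = stats::setNames(ybar - mu, colnames(logmat)),
      gene_solutions = stats::setNames(numeric(m), rownames(logmat)),
      gene_tissue_solutions = matrix(0, m, length(tiss),
                                     dimnames = list(rownames(logmat), tiss)),
      gene_animal_solutions = matrix(0, m, length(anim),
                                     dimnames = list(rownames(logmat), anim)),
      gene_state_solutions = matrix(0, m, length(stat),
                                    dimnames = list(rownames(logmat), stat)),
      variance_components = s2, loglik = ll,
      n_reml_iterations = it, converged = conv,
      tissues = tiss, animals = anim, states = stat
    ), class = "mm_fit")
  }

  s2tot <- sum(R^2) / max(1, (m - 1L) * n)
  comp_names <- c("sigma2_G", "sigma2_GT", "sigma2_GA", "sigma2_GP", "sigma2_e")
  if (s2tot < 1e-12) {
    return(empty_fit(stats::setNames(rep(0, 5), comp_names), TRUE, numeric(0), 0L))
  }
  s2 <- stats::setNames(rep(s2tot / 5, 5), comp_names)

  qs <- c(1, length(tiss), length(anim), length(stat))
  Zs <- list(matrix(1, n, 1), Zt, Za, Zp)
  Cs <- list(J, Ct, Ca, Cp)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    V <- s2[1] * J + s2[2] * Ct + s2[3] * Ca + s2[4] * Cp +
      max(s2[5], 1e-10) * I
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    S <- R %*% Vinv
    ll <- -0.5 * ((m - 1) * 2 * sum(log(diag(ch))) + sum(R * S))
    ll_trace <- c(ll_trace, ll)

    s2_new <- s2
    for (c in 1:4) {
      if (s2[c] <= 0) next
      U <- s2[c] * (S %*% Zs[[c]])
      trc <- sum(Vinv * Cs[[c]])
      s2_new[c] <- (sum(U^2) + s2[c] * (m * qs[c] - s2[c] * (m - 1) * trc)) /
        (m * qs[c])
    }
    if (s2[5] > 0) {
      tre <- sum(diag(Vinv))
      s2_new[5] <- (s2[5]^2 * sum(S^2) +
                      s2[5] * (m * n - s2[5] * (m - 1) * tre)) / (m * n)
    }
    s2_new <- pmax(s2_new, 0)
    rel <- abs(s2_new - s2) / pmax(s2, 1e-8)
    s2 <- s2_new
    # components collapsing to the zero boundary count as converged
    if (all(rel < tol | s2_new < 1e-8 * max(s2_new))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter, " iterations")
  }

  V <- s2[1] * J + s2[2] * Ct + s2[3] * Ca + s2[4] * Cp +
    max(s2[5], 1e-10) * I
  Vinv <- chol2inv(chol(V))
  S <- R %*% Vinv
  fit <- empty_fit(s2, converged, ll_trace, iter)
  fit$gene_solutions[] <- s2[1] * rowSums(S)
  fit$gene_tissue_solutions[] <- s2[2] * (S %*% Zt)
  fit$gene_animal_solutions[] <- s2[3] * (S %*% Za)
  fit$gene_state_solutions[] <- s2[4] * (S %*% Zp)
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("EM-REML mixed-model fit\n")
  cat("  genes:", length(x$gene_solutions),
      " libraries:", length(x$library_effects), "\n")
  cat("  iterations:", x$n_reml_iterations,
      " converged:", x$converged, "\n")
  cat("  variance components:\n")
  print(round(x$variance_components, 6))
  invisible(x)
}

#' Normalized expression from mixed-model solutions
#'
#' The normalized value for gene j in a library with tissue t, animal k
#' and state p is the linear combination of random-effect solutions
#' G_j + GT_jt + GA_jk + GP_jp; the overall mean and library effects are
#' excluded by construction, which is what removes library-level
#' technical variation.
#'
#' @param fit an `mm_fit`.
#' @param sheet sample sheet giving each library's (tissue, animal, state);
#'   all levels must have been seen at fit time.
#' @param allow_unconverged proceed despite a non-converged fit.
#' @return genes x libraries matrix of normalized expression.
#' @export
normalize_expression <- function(fit, sheet, allow_unconverged = FALSE) {
  if (!inherits(fit, "mm_fit")) stop2("fit must be an mm_fit")
  if (!fit$converged && !allow_unconverged) {
    stop2("mixed-model fit did not converge; pass allow_unconverged = TRUE ",
          "to proceed anyway")
  }
  validate_sheet(sheet)
  ti <- match(sheet$tissue, fit$tissues)
  ki <- match(sheet$animal, fit$animals)
  pi <- match(sheet$state, fit$states)
  if (anyNA(ti) || anyNA(ki) || anyNA(pi)) {
    stop2("sheet contains tissue/animal/state levels unseen at fit time")
  }
  norm <- fit$gene_solutions +
    fit$gene_tissue_solutions[, ti, drop = FALSE] +
    fit$gene_animal_solutions[, ki, drop = FALSE] +
    fit$gene_state_solutions[, pi, drop = FALSE]
  colnames(norm) <- sheet$library
  norm
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (abs(max_index - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Clustering validation of normalized expression
#'
#' Hierarchically clusters library profiles (average linkage on
#' 1 - Pearson correlation), cuts at the number of tissues, and reports
#' the adjusted Rand agreement between clusters and tissue labels. In a
#' well-normalized multi-tissue data set libraries should cluster first
#' by tissue.
#'
#' @param norm genes x libraries normalized matrix.
#' @param sheet sample sheet aligned to `norm`.
#' @return list with `labels` (cluster id per library) and `agreement`
#'   (adjusted Rand index in [-1, 1]; 1 by convention for a single
#'   tissue).
#' @export
cluster_check <- function(norm, sheet) {
  sheet <- align_sheet(sheet, norm)
  k <- length(unique(sheet$tissue))
  if (k < 1L) stop2("no tissues in sheet")
  if (k == 1L) {
    return(list(labels = stats::setNames(rep(1L, ncol(norm)), colnames(norm)),
                agreement = 1))
  }
  sds <- apply(norm, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant library profile(s): ",
            paste(colnames(norm)[sds == 0], collapse = ", "))
  }
  cors <- suppressWarnings(stats::cor(norm))
  cors[!is.finite(cors)] <- 0
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels,
       agreement = adjusted_rand_index(labels, sheet$tissue))
}
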
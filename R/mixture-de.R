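#' Per-tissue differential-expression measure
#'
#' For each gene, the DE measure d is the mean normalized expression over
#' the tissue's POST libraries minus the mean over its PRE libraries
#' (log2 units). Large positive (negative) d indicates up- (down-)
#' regulation at puberty.
#'
#' @param norm genes x libraries normalized matrix.
#' @param sheet sample sheet aligned to `norm`.
#' @param tissue tissue label; must have libraries in both states.
#' @return named numeric vector of d values (one per gene).
#' @export
de_measure <- function(norm, sheet, tissue) {
  sheet <- align_sheet(sheet, norm)
  sel <- sheet$tissue == tissue
  if (!any(sel)) stop2("tissue not in sheet: ", tissue)
  post <- sel & sheet$state == "POST"
  pre <- sel & sheet$state == "PRE"
  if (!any(post)) stop2("tissue ", tissue, " has no POST libraries")
  if (!any(pre)) stop2("tissue ", tissue, " has no PRE libraries")
  rowMeans(norm[, post, drop = FALSE]) - rowMeans(norm[, pre, drop = FALSE])
}

# One EM run for a two-component normal mixture from given responsibilities.
.em_mixture <- function(d, resp, tol, max_iter) {
  n <- length(d)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  warned <- TRUE
  for (it in seq_len(max_iter)) {
    w <- colMeans(resp)
    if (any(w < 1e-10)) return(NULL)
    mu <- colSums(resp * d) / (w * n)
    sg <- sqrt(pmax(colSums(resp * (d - rep(mu, each = n))^2) / (w * n),
                    1e-12))
    dens <- cbind(w[1] * stats::dnorm(d, mu[1], sg[1]),
                  w[2] * stats::dnorm(d, mu[2], sg[2]))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      warned <- FALSE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sg, loglik = ll, n_iter = it,
       resp = resp, not_converged = warned, ll_trace = ll_trace)
}

#' Two-component normal mixture with an empirical null
#'
#' Fits, by maximum-likelihood EM with restarts, the mixture
#' \eqn{\pi_0 N(\mu_0, \sigma_0^2) + \pi_1 N(\mu_1, \sigma_1^2)} to a
#' vector of DE measures. The component with the smaller variance is
#' labeled the empirical null (non-DE genes cluster around zero with
#' small variance; its mean and variance are estimated, not assumed).
#' Posterior null probabilities follow from Bayes' rule.
#'
#' @param d numeric vector of DE measures (>= 50 values, nonzero
#'   variance).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of random restarts; the best log-likelihood
#'   wins.
#' @param seed integer seed for the restarts.
#' @return object of class `mixture_fit` with pi0, pi1, mu0, sigma0, mu1,
#'   sigma1, loglik, n_iter, posterior_null, converged, and a
#'   `no_de_signal` flag (pi1 < 0.2 or variance ratio close to 1).
#' @export
fit_mixture <- function(d, tol = 1e-8, max_iter = 1000L, n_starts = 10L,
                        seed = 1L) {
  d <- as.numeric(d)
  nm <- names(d)
  if (length(d) < 50L) stop2("need >= 50 observations")
  if (any(!is.finite(d))) stop2("non-finite DE measures")
  if (stats::sd(d) < 1e-12) stop2("degenerate input: all DE measures equal")
  n <- length(d)

  set.seed(seed, kind = "Mersenne-Twister")
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      # deterministic start: central 80% of |d - median| as the null
      ctr <- abs(d - stats::median(d))
      p_null <- ifelse(ctr <= stats::quantile(ctr, 0.8), 0.95, 0.05)
    } else {
      p_null <- stats::runif(n, 0.25, 0.75)
    }
    fit <- .em_mixture(d, cbind(p_null, 1 - p_null), tol, max_iter)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) stop2("mixture EM failed on all starts")
  if (best$not_converged) {
    warning("mixture EM did not converge; returning best fit")
  }
  null_k <- which.min(best$sigma)
  alt_k <- 3L - null_k
  posterior_null <- best$resp[, null_k]
  names(posterior_null) <- nm
  var_ratio <- (best$sigma[alt_k] / best$sigma[null_k])^2
  structure(list(
    pi0 = unname(best$w[null_k]), pi1 = unname(best$w[alt_k]),
    mu0 = unname(best$mu[null_k]), sigma0 = unname(best$sigma[null_k]),
    mu1 = unname(best$mu[alt_k]), sigma1 = unname(best$sigma[alt_k]),
    loglik = best$loglik, n_iter = best$n_iter,
    posterior_null = posterior_null,
    converged = !best$not_converged,
    no_de_signal = unname(best$w[alt_k] < 0.2 && var_ratio < 4) ||
      var_ratio < 1.5,
    ll_trace = best$ll_trace
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component normal mixture (empirical null)\n")
  cat(sprintf("  null: pi0 = %.3f, N(%.4f, %.4f^2)\n", x$pi0, x$mu0, x$sigma0))
  cat(sprintf("  alt : pi1 = %.3f, N(%.4f, %.4f^2)\n", x$pi1, x$mu1, x$sigma1))
  cat(sprintf("  loglik = %.3f after %d iterations; converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  if (x$no_de_signal) cat("  note: no DE signal detected\n")
  invisible(x)
}

#' Call DE genes at a target mixture-model FDR
#'
#' Genes are ranked by posterior null probability (ascending); the called
#' set is the largest prefix whose mean posterior null probability does
#' not exceed `fdr_target` - the standard mixture-model estimate of the
#' experiment-wise false discovery rate of the called set. Direction is
#' the sign of d, and the fold change uses the signed convention
#' 2^d for d >= 0 and -2^(-d) for d < 0.
#'
#' @param fit a `mixture_fit`.
#' @param d the DE measures the fit was computed from (named by gene).
#' @param fdr_target target FDR in (0, 1), default 0.01.
#' @return data.frame (gene, d, fold_change, posterior_null, is_de,
#'   direction) sorted by posterior_null; its `estimated_fdr` attribute
#'   is the mean posterior null over calls.
#' @export
call_de <- function(fit, d, fdr_target = 0.01) {
  if (!inherits(fit, "mixture_fit")) stop2("fit must be a mixture_fit")
  if (!is.numeric(fdr_target) || length(fdr_target) != 1L ||
      fdr_target <= 0 || fdr_target >= 1) {
    stop2("fdr_target must be in (0, 1)")
  }
  p0 <- fit$posterior_null
  if (length(d) != length(p0)) stop2("d and fit have different lengths")
  ord <- order(p0)
  cum_fdr <- cumsum(p0[ord]) / seq_along(ord)
  n_call <- max(c(0L, which(cum_fdr <= fdr_target)))
  is_de <- logical(length(d))
  is_de[ord[seq_len(n_call)]] <- TRUE
  res <- data.frame(
    gene = if (!is.null(names(d))) names(d) else as.character(seq_along(d)),
    d = as.numeric(d),
    fold_change = ifelse(d >= 0, 2^d, -(2^(-d))),
    posterior_null = as.numeric(p0),
    is_de = is_de,
    direction = ifelse(d > 0, "up", "down")
  )
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "estimated_fdr") <- if (n_call > 0) cum_fdr[n_call] else 0
  res
}
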
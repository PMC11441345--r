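#' Gaussian MLE of a precision matrix with a fixed zero pattern
#'
#' Maximum-likelihood fit of a Gaussian graphical model whose conditional
#' independence structure (zero pattern of the precision matrix) is known,
#' by the classical iterative regression algorithm: each column's regression
#' coefficients are solved exactly on the support, cycling until the working
#' covariance stabilizes. This is an unpenalized estimator, independent of
#' the graphical-lasso path, and serves as the refit engine for
#' [support_search()].
#'
#' @param S Sample correlation/covariance matrix.
#' @param support Logical symmetric matrix; \code{TRUE} where a precision
#'   off-diagonal is free, \code{FALSE} where it is constrained to zero.
#'   The diagonal is ignored (always free).
#' @param tol Convergence tolerance on the working covariance (default 1e-8).
#' @param maxit Maximum sweeps (default 500).
#' @return List with \code{precision}, \code{converged}.
#' @export
constrained_mle <- function(S, support, tol = 1e-8, maxit = 500L) {
  S <- as.matrix(S)
  p <- ncol(S)
  support <- as.matrix(support)
  stopifnot(nrow(support) == p, ncol(support) == p)
  if (!isTRUE(all.equal(support, t(support)))) {
    stop("support pattern must be symmetric")
  }
  W <- S
  B <- matrix(0, p, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    maxdel <- 0
    for (j in seq_len(p)) {
      idx <- setdiff(which(support[, j]), j)
      beta <- numeric(p)
      if (length(idx) > 0L) {
        others <- setdiff(seq_len(p), j)
        W11 <- W[others, others, drop = FALSE]
        s12 <- S[others, j]
        sel <- match(idx, others)
        beta_sub <- solve(W11[sel, sel, drop = FALSE], s12[sel])
        beta[idx] <- beta_sub
        w12 <- as.vector(W11 %*% beta[others])
        maxdel <- max(maxdel, max(abs(W[others, j] - w12)))
        W[others, j] <- w12
        W[j, others] <- w12
      } else {
        others <- setdiff(seq_len(p), j)
        maxdel <- max(maxdel, if (length(others)) max(abs(W[others, j])) else 0)
        W[others, j] <- 0
        W[j, others] <- 0
      }
      B[, j] <- beta
    }
    if (maxdel < tol) {
      converged <- TRUE
      break
    }
  }
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    denom <- W[j, j] - sum(W[others, j] * B[others, j])
    K[j, j] <- 1 / denom
    K[others, j] <- -B[others, j] * K[j, j]
  }
  K <- (K + t(K)) / 2
  K[!support & !diag(p)] <- 0
  list(precision = K, converged = converged)
}

#' Exhaustive EBIC support search (brute-force oracle)
#'
#' Enumerates every possible edge support over \code{p} items (all
#' \code{2^(p(p-1)/2)} sparsity patterns), refits each by the unpenalized
#' constrained ML of [constrained_mle()], scores each with EBIC, and returns
#' the minimizer. Tractable only for small \code{p} (at most 5); intended as
#' an independent cross-check of the penalized-path model selection.
#'
#' @param S Sample correlation matrix.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return List with \code{support} (logical matrix of the selected edges),
#'   \code{precision}, \code{ebic}, and \code{n_patterns} searched.
#' @export
support_search <- function(S, n, gamma = 0.5) {
  S <- as.matrix(S)
  p <- ncol(S)
  if (p > 5L) stop("exhaustive support search supported for p <= 5 only")
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- NULL
  for (code in 0:(2^m - 1)) {
    sup <- matrix(FALSE, p, p)
    for (e in seq_len(m)) {
      if (bitwAnd(bitwShiftR(code, e - 1L), 1L) == 1L) {
        sup[pairs[e, 1], pairs[e, 2]] <- TRUE
        sup[pairs[e, 2], pairs[e, 1]] <- TRUE
      }
    }
    fit <- constrained_mle(S, sup)
    if (!fit$converged) next
    K <- fit$precision
    ld <- determinant(K, logarithm = TRUE)
    if (ld$sign <= 0) next
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
    E <- sum(sup[upper.tri(sup)])
    ebic <- -2 * ll + E * log(n) + 4 * E * gamma * log(max(p, 2))
    if (is.null(best) || ebic < best$ebic - 1e-9 ||
        (abs(ebic - best$ebic) <= 1e-9 && E < best$E)) {
      best <- list(support = sup, precision = K, ebic = ebic, E = E)
    }
  }
  if (is.null(best)) stop("no sparsity pattern admitted a valid ML fit")
  list(support = best$support, precision = best$precision,
       ebic = best$ebic, n_patterns = 2^m)
}
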
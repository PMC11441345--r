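#' Control parameters for network estimation
#'
#' @param gamma EBIC hyperparameter (default 0.5); 0 recovers ordinary BIC.
#' @param lambda_min_ratio Smallest graphical-lasso penalty as a fraction of
#'   the largest (default 0.01). The largest penalty is the maximum absolute
#'   off-diagonal correlation, at which the selected network is empty.
#' @param n_lambda Number of log-spaced penalties on the path (default 100).
#' @param alpha Two-sided significance level for the non-regularized
#'   estimator (default 0.05).
#' @param min_variance Variance floor below which an item is treated as
#'   constant (default 1e-10).
#' @param min_n Smallest sample size at which estimation is attempted
#'   (default 10); a warning is emitted below 100, where small-sample
#'   instability is expected.
#' @param tol Convergence tolerance of the block coordinate descent,
#'   relative to the mean absolute off-diagonal correlation (default 1e-4).
#' @param maxit Maximum outer/inner iterations (default 200).
#' @param penalize_diagonal Whether the L1 penalty also applies to the
#'   precision diagonal (default FALSE, the convention of the reference
#'   EBIC-glasso implementations; penalizing the diagonal biases model
#'   selection toward dense models).
#' @return An object of class \code{"ggm_control"}.
#' @export
ggm_control <- function(gamma = 0.5, lambda_min_ratio = 0.01,
                        n_lambda = 100L, alpha = 0.05,
                        min_variance = 1e-10, min_n = 10L,
                        tol = 1e-4, maxit = 200L,
                        penalize_diagonal = FALSE) {
  stopifnot(gamma >= 0, lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_lambda >= 2, alpha > 0, alpha <= 1, min_variance >= 0,
            min_n >= 2, tol > 0, maxit >= 1, is.logical(penalize_diagonal))
  structure(list(gamma = gamma, lambda_min_ratio = lambda_min_ratio,
                 n_lambda = as.integer(n_lambda), alpha = alpha,
                 min_variance = min_variance, min_n = as.integer(min_n),
                 tol = tol, maxit = as.integer(maxit),
                 penalize_diagonal = isTRUE(penalize_diagonal)),
            class = "ggm_control")
}

#' Pearson correlation matrix with degeneracy checks
#'
#' @param data Numeric matrix, one row per observation, at least two
#'   columns. Rows with missing values are removed (listwise deletion).
#' @param min_variance Variance floor; a column at or below it raises a
#'   degenerate-item error naming the column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(data, min_variance = 1e-10) {
  x <- as.matrix(data)
  if (ncol(x) < 2L) stop("need at least two items to correlate")
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least three complete observations")
  v <- apply(x, 2L, stats::var)
  if (any(v <= min_variance)) {
    bad <- colnames(x)[which(v <= min_variance)]
    if (is.null(bad)) bad <- which(v <= min_variance)
    stop("degenerate (constant) item(s): ", paste(bad, collapse = ", "))
  }
  S <- cor(x)
  (S + t(S)) / 2
}

#' Graphical-lasso path with EBIC
#'
#' Solves the L1-penalized Gaussian maximum-likelihood precision problem at
#' \code{n_lambda} log-spaced penalties from \code{lambda_max} (the largest
#' absolute off-diagonal of \code{S}, where the solution is diagonal) down to
#' \code{lambda_min_ratio * lambda_max}, with warm starts, and computes for
#' each solution the log-likelihood
#' \eqn{\ell = (n/2)(\log\det K - \mathrm{tr}(SK))} and
#' \eqn{EBIC = -2\ell + E\log n + 4E\gamma\log p}, where \eqn{E} is the
#' number of nonzero upper-triangle precision entries.
#'
#' @param S Correlation (or covariance) matrix.
#' @param n Sample size behind \code{S}; must exceed the number of items.
#' @param control A [ggm_control()].
#' @return An object of class \code{"glasso_path"}: list with
#'   \code{lambda}, \code{precision} (p x p x n_lambda array), \code{edges},
#'   \code{loglik}, \code{ebic}, \code{converged}, \code{n}, \code{p},
#'   \code{gamma}. Path points that failed to converge are flagged and
#'   skipped by [select_ebic()] with a warning.
#' @export
glasso_path <- function(S, n, control = ggm_control()) {
  S <- as.matrix(S)
  p <- ncol(S)
  stopifnot(nrow(S) == p, p >= 1)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  if (n < p + 1L) stop("sample size must exceed the number of items")
  off <- abs(S[upper.tri(S)])
  lambda_max <- if (length(off)) max(off) else 0
  if (lambda_max < 1e-12) {
    # independence: the solution is diagonal at any penalty
    lambdas <- 0
  } else {
    lambdas <- exp(seq(log(lambda_max),
                       log(control$lambda_min_ratio * lambda_max),
                       length.out = control$n_lambda))
  }
  res <- glasso_path_cpp(S, lambdas, control$tol, control$maxit,
                         control$penalize_diagonal)
  loglik <- (n / 2) * (res$logdet - res$trace_s_theta)
  ebic <- -2 * loglik + res$edges * log(n) +
    4 * res$edges * control$gamma * log(max(p, 2))
  structure(list(lambda = lambdas, precision = res$precision,
                 edges = as.integer(res$edges), loglik = loglik,
                 ebic = ebic, converged = res$converged,
                 n = n, p = p, gamma = control$gamma, S = S),
            class = "glasso_path")
}

# precision matrix -> partial correlations, preserving exact zeros
precision_to_pcor_matrix <- function(K) {
  d <- diag(K)
  pc <- -K / sqrt(outer(d, d))
  pc[K == 0] <- 0
  diag(pc) <- 0
  (pc + t(pc)) / 2
}

#' Convert a precision matrix to partial correlations
#'
#' \eqn{pcor_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}}, with an exactly zero
#' diagonal; structural zeros of \code{K} remain exactly zero.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Partial-correlation matrix.
#' @export
precision_to_pcor <- function(K) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  precision_to_pcor_matrix(K)
}

new_symptom_network <- function(items, pcor, method, n, lambda = NA_real_,
                                alpha = NA_real_, ebic = NA_real_,
                                converged = TRUE, dropped_items = character(),
                                call = NULL) {
  structure(list(items = items, pcor = pcor, method = method, n = n,
                 lambda = lambda, alpha = alpha, ebic = ebic,
                 converged = converged, dropped_items = dropped_items,
                 call = call),
            class = "symptom_network")
}

#' Select the minimum-EBIC model on a glasso path
#'
#' Scores every distinct edge support appearing among the converged path
#' points by the EBIC of its unpenalized constrained maximum-likelihood
#' refit (relaxed graphical lasso: the penalty path proposes candidate
#' sparsity patterns; each candidate is then scored without shrinkage, so
#' strong true edges do not drag the selection toward dense models), and
#' returns the minimizer as a partial-correlation network. Exact EBIC ties
#' go to the sparser support, then to the larger penalty.
#'
#' @param path A [glasso_path()] object.
#' @param items Optional item labels for the network nodes.
#' @return A \code{"symptom_network"} object (see [symptom_network()]).
#' @export
select_ebic <- function(path, items = NULL) {
  stopifnot(inherits(path, "glasso_path"))
  ok <- as.logical(path$converged) & is.finite(path$ebic)
  if (!any(ok)) {
    stop("no penalty on the path converged to a valid model")
  }
  if (!all(ok)) {
    warning(sprintf("%d of %d path points failed to converge and were skipped",
                    sum(!ok), length(ok)))
  }
  p <- path$p
  idx <- which(ok)
  ut <- upper.tri(matrix(0, p, p))
  sig <- vapply(idx, function(i) {
    paste(which(path$precision[, , i][ut] != 0), collapse = ",")
  }, character(1))
  first <- idx[!duplicated(sig)]  # first occurrence = largest lambda
  best <- NULL
  for (i in first) {
    sup <- matrix(0L, p, p)
    sup[ut][path$precision[, , i][ut] != 0] <- 1L
    sup <- sup + t(sup)
    fit <- constrained_mle_cpp(path$S, sup, 1e-8, 500L)
    if (!isTRUE(fit$converged)) next
    E <- sum(sup[ut])
    ll <- (path$n / 2) * (fit$logdet - fit$trace_s_theta)
    ebic <- -2 * ll + E * log(path$n) + 4 * E * path$gamma * log(max(p, 2))
    if (is.null(best) || ebic < best$ebic - 1e-9 ||
        (abs(ebic - best$ebic) <= 1e-9 && E < best$E)) {
      best <- list(K = fit$precision, ebic = ebic, E = E,
                   lambda = path$lambda[i])
    }
  }
  if (is.null(best)) stop("no path support admitted a valid ML refit")
  if (is.null(items)) items <- paste0("item", seq_len(p))
  pc <- precision_to_pcor_matrix(best$K)
  dimnames(pc) <- list(items, items)
  new_symptom_network(items = items, pcor = pc, method = "ebic_glasso",
                      n = path$n, lambda = best$lambda,
                      ebic = best$ebic, converged = TRUE)
}

# full partial correlations by correlation-matrix inversion
invert_to_pcor <- function(S) {
  K <- tryCatch(solve(S), error = function(e) {
    stop("correlation matrix is singular; use the regularized ",
         "(ebic_glasso) estimator", call. = FALSE)
  })
  precision_to_pcor_matrix(K)
}

# Fisher-z two-sided p-values for partial correlations of order p - 2
pcor_pvalues <- function(pc, n, p) {
  eff <- n - (p - 2) - 3  # effective sample size n - (p-2), minus 3
  if (eff <= 0) stop("sample too small for the non-regularized edge test")
  z <- atanh(pmin(pmax(pc, -1 + 1e-12), 1 - 1e-12))
  pv <- 2 * pnorm(-abs(z) * sqrt(eff))
  diag(pv) <- 1
  pv
}

#' Fit a within-profile symptom network
#'
#' The central model-fitting function: estimates a Gaussian graphical model
#' (partial-correlation network) from continuous/ordinal item scores.
#' Two estimators are available:
#' \describe{
#'   \item{\code{"ebic_glasso"}}{graphical lasso over a log-spaced penalty
#'     path with the minimum-EBIC model selected (the regularized estimator,
#'     \code{gamma = 0.5} by default); false-positive edges are suppressed
#'     by the L1 penalty.}
#'   \item{\code{"nonreg"}}{full partial correlations from the inverse
#'     correlation matrix, with each edge tested by the Fisher z transform
#'     at effective degrees of freedom \code{n - 2 - (p - 2)}; edges with
#'     two-sided p >= alpha are set to zero (no multiplicity correction).
#'     This is the small-sample fallback used when the regularized path
#'     fails to converge.}
#' }
#'
#' @param data Numeric matrix or data frame of item scores, one row per
#'   respondent, one column per retained item.
#' @param method \code{"ebic_glasso"} (default) or \code{"nonreg"}.
#' @param control A [ggm_control()].
#' @param items Optional item labels (default: column names).
#' @return An object of class \code{"symptom_network"} with elements
#'   \code{items}, \code{pcor} (symmetric partial-correlation matrix, zero
#'   diagonal), \code{method}, \code{n}, and the selected \code{lambda} /
#'   \code{alpha} and \code{ebic} metadata. Methods: \code{print},
#'   \code{summary}, \code{coef} (the pcor matrix), \code{plot},
#'   \code{simulate}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), ncol = 3)
#' x[, 2] <- x[, 2] + 0.8 * x[, 1]
#' net <- symptom_network(x)
#' coef(net)
#' @export
symptom_network <- function(data, method = c("ebic_glasso", "nonreg"),
                            control = ggm_control(), items = NULL) {
  method <- match.arg(method)
  cl <- match.call()
  x <- as.matrix(data)
  if (is.null(items)) {
    items <- colnames(x)
    if (is.null(items)) items <- paste0("item", seq_len(ncol(x)))
  }
  n <- sum(complete.cases(x))
  if (n < control$min_n) {
    stop(sprintf("sample size %d is below the estimation floor of %d",
                 n, control$min_n))
  }
  if (n < 100L) {
    warning(sprintf(
      "sample size %d is small (< 100); estimates may be unstable", n))
  }
  p <- ncol(x)
  S <- sample_correlation(x, control$min_variance)
  if (method == "ebic_glasso") {
    path <- glasso_path(S, n, control)
    net <- select_ebic(path, items = items)
  } else {
    if (n <= p + 2L) stop("nonreg estimator requires n > p + 2")
    pc <- invert_to_pcor(S)
    pv <- pcor_pvalues(pc, n, p)
    pc[pv >= control$alpha] <- 0
    diag(pc) <- 0
    dimnames(pc) <- list(items, items)
    net <- new_symptom_network(items = items, pcor = pc, method = "nonreg",
                               n = n, alpha = control$alpha)
  }
  net$call <- cl
  net
}

#' Extract the subsample of respondents matched to a profile
#'
#' Returns the raw (0-3) item scores of the profile's members, restricted to
#' the items marked present in the profile. Absent items are constant zero
#' within the subsample — the Gaussian graphical model is undefined for
#' constant variables — so they are dropped and recorded in the
#' \code{"dropped_items"} attribute.
#'
#' @param responses A matched [response_matrix()].
#' @param catalog The catalog used for matching.
#' @param profile_id Catalog ID of the profile.
#' @param min_n Smallest admissible subsample (default 10); fewer members
#'   raise a too-small-sample error.
#' @return Numeric matrix of the present items' scores, with the dropped
#'   (absent) item labels in \code{attr(, "dropped_items")}.
#' @export
profile_subsample <- function(responses, catalog, profile_id, min_n = 10L) {
  stopifnot(inherits(responses, "response_matrix"),
            inherits(catalog, "profile_catalog"))
  profile_id <- stopifnot_scalar_count(profile_id, "profile_id")
  rows <- which(!is.na(responses$profile_id) &
                responses$profile_id == profile_id)
  if (length(rows) < min_n) {
    stop(sprintf(
      "profile %d has %d member(s), below the estimation floor of %d",
      profile_id, length(rows), min_n))
  }
  present <- which(catalog$presence[profile_id, ] == 1L)
  out <- responses$scores[rows, present, drop = FALSE]
  dropped <- colnames(responses$scores)[setdiff(seq_len(ncol(responses$scores)),
                                                present)]
  attr(out, "dropped_items") <- dropped
  out
}

#' Strength centrality of a network
#'
#' Per-item strength (sum of absolute incident edge weights), its z-scored
#' version across items, and the strength rank (rank 1 = highest, ties
#' broken by item order). When all strengths are equal the z-score is
#' undefined and flagged via the \code{"degenerate"} attribute.
#'
#' @param network A \code{"symptom_network"} or a symmetric weight matrix.
#' @return Data frame with columns \code{item}, \code{strength},
#'   \code{z_strength}, \code{rank}.
#' @export
strength_centrality <- function(network) {
  w <- if (inherits(network, "symptom_network")) network$pcor
       else as.matrix(network)
  if (ncol(w) < 2L) stop("strength centrality needs at least two items")
  s <- rowSums(abs(w))
  items <- rownames(w)
  if (is.null(items)) items <- paste0("item", seq_along(s))
  degenerate <- sd(s) == 0
  z <- if (degenerate) rep(NA_real_, length(s)) else (s - mean(s)) / sd(s)
  out <- data.frame(item = items, strength = unname(s),
                    z_strength = unname(z),
                    rank = rank(-s, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Force-directed (Fruchterman-Reingold) node layout
#'
#' Computes a deterministic weighted Fruchterman-Reingold layout with
#' absolute partial correlations as attraction weights, rescaled to the unit
#' square.
#'
#' @param network A \code{"symptom_network"}.
#' @param seed Integer seed making the layout reproducible (default 42).
#' @return Data frame with columns \code{item}, \code{x}, \code{y} in
#'   \code{[0, 1]}.
#' @export
network_layout <- function(network, seed = 42L) {
  stopifnot(inherits(network, "symptom_network"))
  w <- abs(network$pcor)
  p <- ncol(w)
  if (p == 1L) {
    return(data.frame(item = network$items, x = 0.5, y = 0.5,
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  xy <- with_seed(seed, {
    if (igraph::ecount(g) > 0) {
      igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
    } else {
      igraph::layout_in_circle(g)
    }
  })
  rescale01 <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  data.frame(item = network$items, x = rescale01(xy[, 1]),
             y = rescale01(xy[, 2]), stringsAsFactors = FALSE)
}

# ---- S3 methods for symptom_network ----------------------------------------

#' @export
print.symptom_network <- function(x, ...) {
  e <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat(sprintf("Symptom network (%s): %d items, %d edges, n = %d\n",
              x$method, length(x$items), e, x$n))
  if (x$method == "ebic_glasso") {
    cat(sprintf("  selected lambda = %.4g, EBIC = %.2f\n", x$lambda, x$ebic))
  } else {
    cat(sprintf("  edge test alpha = %.3g (Fisher z)\n", x$alpha))
  }
  if (length(x$dropped_items)) {
    cat("  dropped constant/absent items:",
        paste(x$dropped_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.symptom_network <- function(object, ...) {
  pc <- object$pcor
  ut <- pc[upper.tri(pc)]
  edges <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  el <- data.frame(item_a = object$items[edges[, 1]],
                   item_b = object$items[edges[, 2]],
                   pcor = pc[edges], stringsAsFactors = FALSE)
  el <- el[order(-abs(el$pcor)), , drop = FALSE]
  out <- list(network = object, edges = el,
              density = if (length(ut)) mean(ut != 0) else 0,
              centrality = strength_centrality(object))
  class(out) <- "summary.symptom_network"
  out
}

#' @export
print.summary.symptom_network <- function(x, max_edges = 10L, ...) {
  print(x$network)
  cat(sprintf("  density = %.2f\n", x$density))
  if (nrow(x$edges)) {
    cat("Strongest edges:\n")
    show <- utils::head(x$edges, max_edges)
    show$pcor <- round(show$pcor, 3)
    print(show, row.names = FALSE)
  }
  cat("Strength centrality:\n")
  cent <- x$centrality
  cent$strength <- round(cent$strength, 3)
  cent$z_strength <- round(cent$z_strength, 2)
  print(cent[order(cent$rank), ], row.names = FALSE)
  invisible(x)
}

#' @export
coef.symptom_network <- function(object, ...) object$pcor

#' @export
plot.symptom_network <- function(x, seed = 42L, vertex_scale = 18, ...) {
  lay <- network_layout(x, seed = seed)
  w <- abs(x$pcor)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ecol <- grDevices::adjustcolor(
    ifelse(x$pcor[igraph::as_edgelist(g, names = FALSE)] >= 0,
           "forestgreen", "firebrick"), 0.8)
  igraph::plot.igraph(
    g, layout = as.matrix(lay[, c("x", "y")]),
    vertex.size = vertex_scale, vertex.label = x$items,
    vertex.color = "lightsteelblue1",
    edge.width = if (igraph::ecount(g)) 8 * igraph::E(g)$weight else 1,
    edge.color = if (igraph::ecount(g)) ecol else NULL, ...)
  invisible(lay)
}

#' Simulate latent-scale data from a fitted network
#'
#' Draws multivariate normal observations whose partial-correlation
#' structure equals the fitted network (precision with unit diagonal and
#' off-diagonals \code{-pcor}), on the latent (continuous) scale.
#'
#' @param object A \code{"symptom_network"} whose implied precision is
#'   positive definite.
#' @param nsim Number of observations.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Numeric matrix \code{nsim} x items.
#' @export
simulate.symptom_network <- function(object, nsim = 1L, seed = NULL, ...) {
  K <- pcor_to_precision(object$pcor)
  Sigma <- solve(K)
  L <- chol(Sigma)
  draw <- function() {
    matrix(rnorm(nsim * ncol(K)), nrow = nsim) %*% L
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  colnames(x) <- object$items
  x
}
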
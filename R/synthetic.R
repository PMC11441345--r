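#' Convert partial correlations to a precision matrix
#'
#' Builds the precision matrix with unit diagonal and off-diagonals
#' \code{-pcor[i, j]}, validating positive definiteness. This is the inverse
#' of the transform used when reading partial correlations off an estimated
#' precision matrix, and the canonical parameterization of synthetic ground
#' truth (unit latent variances; all association structure in the precision
#' matrix).
#'
#' @param pcor Symmetric partial-correlation matrix (zero diagonal,
#'   entries in (-1, 1)).
#' @return Positive-definite precision matrix.
#' @export
pcor_to_precision <- function(pcor) {
  pcor <- as.matrix(pcor)
  p <- ncol(pcor)
  stopifnot(nrow(pcor) == p)
  if (max(abs(pcor - t(pcor))) > 1e-10) stop("pcor must be symmetric")
  if (any(abs(pcor[upper.tri(pcor)]) >= 1)) {
    stop("partial correlations must lie strictly inside (-1, 1)")
  }
  K <- -pcor
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("invalid specification: implied precision matrix is not ",
         "positive definite")
  }
  K
}

#' Random sparse partial-correlation ground truth
#'
#' Draws a random edge set of the requested size with weights uniform in
#' \code{weight_range} and random signs (optional), then shrinks all weights
#' by factors of 0.9 until the implied precision matrix is positive
#' definite. Deterministic given the seed.
#'
#' @param p Number of items.
#' @param n_edges Number of nonzero edges.
#' @param weight_range Length-2 numeric range of absolute edge weights.
#' @param seed Integer seed.
#' @param negative_prob Probability that an edge weight is negative
#'   (default 0: all positive, the typical sign in symptom networks).
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
random_sparse_pcor <- function(p, n_edges, weight_range = c(0.25, 0.35),
                               seed = 1L, negative_prob = 0) {
  stopifnot(p >= 2, n_edges >= 0, n_edges <= p * (p - 1) / 2)
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    sel <- sample.int(nrow(pairs), n_edges)
    w <- stats::runif(n_edges, weight_range[1], weight_range[2])
    sgn <- ifelse(stats::runif(n_edges) < negative_prob, -1, 1)
    pc <- matrix(0, p, p)
    for (e in seq_len(n_edges)) {
      pc[pairs[sel[e], 1], pairs[sel[e], 2]] <- w[e] * sgn[e]
      pc[pairs[sel[e], 2], pairs[sel[e], 1]] <- w[e] * sgn[e]
    }
    for (tries in 1:100) {
      ok <- tryCatch({
        pcor_to_precision(pc)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      pc <- pc * 0.9
    }
    pc
  })
}

#' Define a planted subpopulation
#'
#' One mixture component of a synthetic cohort: a fixed dichotomized profile,
#' a mixing weight, a ground-truth partial-correlation network over the
#' profile's present items, and the per-item latent thresholds that map the
#' latent normal scale onto ordinal scores.
#'
#' @param profile Presence pattern: 0/1 vector of length k or a pattern
#'   string such as \code{"111111100"}.
#' @param weight Positive mixing weight.
#' @param pcor Ground-truth partial-correlation matrix over the present
#'   items (default: empty network).
#' @param thresholds Strictly increasing latent cut points, either a vector
#'   of length \code{max_item_score - 1} shared by all present items or a
#'   matrix with one row per present item. Defaults to standard-normal
#'   tertiles, giving equal mass to scores 1, 2 and 3.
#' @return An object of class \code{"subpopulation"}.
#' @export
subpopulation <- function(profile, weight = 1, pcor = NULL,
                          thresholds = NULL) {
  if (is.character(profile)) profile <- pattern_vector(profile)
  profile <- as.integer(profile)
  stopifnot(all(profile %in% c(0L, 1L)), weight > 0)
  m <- sum(profile)
  if (m == 0L) stop("a planted profile must have at least one present item")
  if (is.null(pcor)) pcor <- matrix(0, m, m)
  pcor <- as.matrix(pcor)
  if (ncol(pcor) != m) {
    stop("pcor dimension must equal the number of present items")
  }
  pcor_to_precision(pcor)  # validate
  structure(list(profile = profile, weight = weight, pcor = pcor,
                 thresholds = thresholds),
            class = "subpopulation")
}

#' Specification of a synthetic questionnaire cohort
#'
#' A mixture of planted subpopulations observed as ordinal item scores.
#' Respondents of each subpopulation draw a latent multivariate normal with
#' covariance implied by the subpopulation's precision matrix; each present
#' item is discretized through its thresholds into scores 1..max_item_score
#' (present items never score 0, so the dichotomized pattern of every
#' generated respondent equals the planted profile exactly), and absent
#' items are fixed at 0.
#'
#' @param n Number of respondents.
#' @param subpops List of [subpopulation()] objects; weights are normalized
#'   to sum to 1.
#' @param n_items Item count k (default 9).
#' @param max_item_score Maximum item score (default 3).
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n, subpops, n_items = 9L, max_item_score = 3L,
                           seed = 1L) {
  n <- stopifnot_scalar_count(n, "n")
  if (inherits(subpops, "subpopulation")) subpops <- list(subpops)
  stopifnot(length(subpops) >= 1,
            all(vapply(subpops, inherits, logical(1), "subpopulation")))
  for (sp in subpops) {
    if (length(sp$profile) != n_items) {
      stop("subpopulation profile length must equal n_items")
    }
  }
  w <- vapply(subpops, `[[`, numeric(1), "weight")
  default_thr <- qnorm(seq_len(max_item_score - 1) / max_item_score)
  subpops <- lapply(subpops, function(sp) {
    thr <- if (is.null(sp$thresholds)) default_thr else sp$thresholds
    if (!is.matrix(thr)) {
      thr <- matrix(thr, nrow = sum(sp$profile),
                    ncol = max_item_score - 1, byrow = TRUE)
    }
    if (ncol(thr) != max_item_score - 1 || nrow(thr) != sum(sp$profile)) {
      stop("thresholds must give max_item_score - 1 cut points per ",
           "present item")
    }
    if (any(apply(thr, 1L, function(r) any(diff(r) <= 0)))) {
      stop("thresholds must be strictly increasing per item")
    }
    sp$thresholds <- thr
    sp
  })
  structure(list(n = n, subpops = subpops, weights = w / sum(w),
                 n_items = as.integer(n_items),
                 max_item_score = as.integer(max_item_score),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort
#'
#' Samples the cohort defined by a [synthetic_spec()]: subpopulation
#' membership by the mixing weights, latent multivariate normal scores per
#' subpopulation, threshold discretization of present items into
#' \code{1..max_item_score}, absent items at 0. Deterministic given the
#' spec's seed. The planted subpopulation index of every respondent is kept
#' in the \code{"planted"} attribute.
#'
#' @param spec A [synthetic_spec()].
#' @return A [response_matrix()] (pre-matching), with item columns
#'   \code{phq1..phqk}.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_items
  with_seed(spec$seed, {
    member <- sample.int(length(spec$subpops), spec$n, replace = TRUE,
                         prob = spec$weights)
    scores <- matrix(0L, nrow = spec$n, ncol = k,
                     dimnames = list(NULL, paste0("phq", seq_len(k))))
    for (s in seq_along(spec$subpops)) {
      rows <- which(member == s)
      if (!length(rows)) next
      sp <- spec$subpops[[s]]
      present <- which(sp$profile == 1L)
      m <- length(present)
      K <- pcor_to_precision(sp$pcor)
      Sigma <- solve(K)
      L <- chol(Sigma)
      z <- matrix(rnorm(length(rows) * m), nrow = length(rows)) %*% L
      z <- sweep(z, 2L, sqrt(diag(Sigma)), "/")  # unit-variance latent scale
      for (j in seq_len(m)) {
        scores[rows, present[j]] <-
          findInterval(z[, j], sp$thresholds[j, ]) + 1L
      }
    }
    out <- response_matrix(scores,
                           ids = sprintf("S%05d", seq_len(spec$n)),
                           max_item_score = spec$max_item_score)
    attr(out, "planted") <- member
    attr(out, "spec") <- spec
    out
  })
}

#' Expected inclusion rate of a planted profile
#'
#' Probability that a respondent generated from a subpopulation reaches a
#' raw-total threshold, computed by exact convolution of the per-item score
#' distributions implied by the thresholds under latent independence. For a
#' correlated ground-truth network this is an approximation (the item
#' marginals are exact; only the joint is not), adequate for calibrating a
#' planted cohort's pass rate.
#'
#' @param subpop A [subpopulation()] (thresholds must be resolved, i.e. the
#'   subpopulation must come from a [synthetic_spec()]), or a
#'   \code{synthetic_spec} whose first subpopulation is used.
#' @param threshold Raw-total inclusion threshold (default 10).
#' @param max_item_score Maximum item score (default 3).
#' @return Probability in \code{[0, 1]}.
#' @export
inclusion_rate <- function(subpop, threshold = 10L, max_item_score = 3L) {
  if (inherits(subpop, "synthetic_spec")) {
    max_item_score <- subpop$max_item_score
    subpop <- subpop$subpops[[1]]
  }
  stopifnot(inherits(subpop, "subpopulation"))
  thr <- subpop$thresholds
  if (is.null(thr)) {
    thr <- matrix(qnorm(seq_len(max_item_score - 1) / max_item_score),
                  nrow = sum(subpop$profile), ncol = max_item_score - 1,
                  byrow = TRUE)
  }
  # per-item probabilities of scores 1..max over the present items
  dist <- c(1, numeric(0))  # distribution of the running total, P(total = 0)
  for (j in seq_len(nrow(thr))) {
    cuts <- c(pnorm(thr[j, ]), 1)
    probs <- diff(c(0, cuts))  # scores 1..max_item_score
    new <- numeric(length(dist) + max_item_score)
    for (s in seq_len(max_item_score)) {
      new[seq_along(dist) + s] <- new[seq_along(dist) + s] + dist * probs[s]
    }
    dist <- new
  }
  # dist[t + 1] = P(total = t) with absent items contributing 0
  sum(dist[seq(threshold + 1L, length(dist))])
}

#' Ground-truth recovery experiment
#'
#' Generates a single-subpopulation cohort, estimates its network on the
#' present items, and scores recovery of the planted edge weights: the
#' Pearson correlation between true and estimated upper-triangle weights,
#' and sensitivity/specificity of exact-zero edge classification.
#'
#' @param spec A single-subpopulation [synthetic_spec()].
#' @param control A [ggm_control()].
#' @param method Estimator passed to [symptom_network()].
#' @return List of class \code{"recovery_experiment"} with elements
#'   \code{network}, \code{truth}, \code{edge_correlation},
#'   \code{sensitivity}, \code{specificity}, \code{n}.
#' @export
recovery_experiment <- function(spec, control = ggm_control(),
                                method = c("ebic_glasso", "nonreg")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$subpops) != 1L) {
    stop("recovery experiments are defined for single-subpopulation specs")
  }
  cohort <- sample_cohort(spec)
  present <- which(spec$subpops[[1]]$profile == 1L)
  x <- cohort$scores[, present, drop = FALSE]
  net <- suppressWarnings(symptom_network(x, method = method,
                                          control = control))
  truth <- spec$subpops[[1]]$pcor
  tv <- upper_vec(truth)
  ev <- upper_vec(net$pcor)
  edge_correlation <- if (sd(tv) > 0 && sd(ev) > 0) cor(tv, ev) else NA_real_
  sens <- if (any(tv != 0)) mean(ev[tv != 0] != 0) else NA_real_
  spec_ <- if (any(tv == 0)) mean(ev[tv == 0] == 0) else NA_real_
  structure(list(network = net, truth = truth,
                 edge_correlation = edge_correlation,
                 sensitivity = sens, specificity = spec_,
                 n = spec$n),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf(
    "Recovery (n = %d, %s): edge correlation %.3f, sens %.2f, spec %.2f\n",
    x$n, x$network$method, x$edge_correlation, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Read a synthetic-cohort specification from YAML
#'
#' Expected layout: top-level \code{n_respondents} (the bare key \code{n}
#' is a YAML 1.1 boolean and cannot be used), \code{seed}, optional
#' \code{n_items} and \code{max_item_score}, and a list
#' \code{subpopulations} of entries with \code{profile} (pattern string),
#' \code{weight}, optional \code{edges} (list of
#' \code{[item_a, item_b, pcor]} over present-item indices) and optional
#' \code{thresholds}.
#'
#' @param path YAML file path.
#' @return A [synthetic_spec()].
#' @export
read_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$n_respondents)) stop("spec file must set 'n_respondents'")
  n_items <- if (is.null(y$n_items)) 9L else as.integer(y$n_items)
  max_score <- if (is.null(y$max_item_score)) 3L else
    as.integer(y$max_item_score)
  subpops <- lapply(y$subpopulations, function(sp) {
    profile <- pattern_vector(as.character(sp$profile))
    m <- sum(profile)
    pc <- matrix(0, m, m)
    for (e in sp$edges) {
      pc[e[[1]], e[[2]]] <- e[[3]]
      pc[e[[2]], e[[1]]] <- e[[3]]
    }
    thr <- if (is.null(sp$thresholds)) NULL else as.numeric(sp$thresholds)
    subpopulation(profile, weight = sp$weight, pcor = pc, thresholds = thr)
  })
  synthetic_spec(n = y$n_respondents, subpops = subpops, n_items = n_items,
                 max_item_score = max_score,
                 seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

#' Export a spec's ground-truth edge list
#'
#' One row per subpopulation edge: subpopulation index, present-item labels
#' and the true partial correlation.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(spec, path) {
  rows <- list()
  for (s in seq_along(spec$subpops)) {
    sp <- spec$subpops[[s]]
    present <- which(sp$profile == 1L)
    idx <- which(upper.tri(sp$pcor) & sp$pcor != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subpopulation = s,
        item_a = paste0("phq", present[idx[, 1]]),
        item_b = paste0("phq", present[idx[, 2]]),
        pcor = sp$pcor[idx], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subpopulation = integer(), item_a = character(),
               item_b = character(), pcor = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
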
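#' Bootstrap configuration for stability analyses
#'
#' @param n_boot Resamples per analysis (default 1000, matching common
#'   practice for edge-accuracy bootstraps; reduce for desk-scale runs).
#' @param drop_proportions Case-dropping grid (default 0.05 to 0.75 in steps
#'   of 0.05; the CS coefficient is conventionally reported up to 75%
#'   dropped).
#' @param cs_correlation Target correlation with the full-sample centrality
#'   (default 0.7).
#' @param cs_probability Required probability of reaching the target
#'   correlation (default 0.95).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class \code{"boot_config"}.
#' @export
boot_config <- function(n_boot = 1000L,
                        drop_proportions = seq(0.05, 0.75, by = 0.05),
                        cs_correlation = 0.7, cs_probability = 0.95,
                        seed = 1L) {
  stopifnot(n_boot >= 1, all(drop_proportions > 0),
            all(drop_proportions < 1), cs_correlation > 0,
            cs_correlation < 1, cs_probability > 0, cs_probability <= 1)
  structure(list(n_boot = as.integer(n_boot),
                 drop_proportions = sort(unique(drop_proportions)),
                 cs_correlation = cs_correlation,
                 cs_probability = cs_probability,
                 seed = as.integer(seed)),
            class = "boot_config")
}

# single estimation step shared by the bootstraps: data -> pcor matrix
fit_pcor <- function(x, method, control) {
  suppressWarnings(
    symptom_network(x, method = method, control = control)$pcor)
}

#' Nonparametric bootstrap edge-accuracy intervals
#'
#' Draws \code{n_boot} row resamples with replacement (each of the original
#' size), re-estimates the network on each with the same configuration, and
#' reports per-edge bootstrap means and 2.5/97.5 percentile intervals.
#' Resamples on which estimation fails are dropped and counted; more than
#' 50% failures aborts with a stability-failure error.
#'
#' @param data Item-score matrix (rows = respondents).
#' @param control A [ggm_control()].
#' @param boot A [boot_config()].
#' @param method Estimator passed to [symptom_network()].
#' @return Data frame of class \code{"edge_accuracy"} with columns
#'   \code{item_a}, \code{item_b}, \code{estimate} (full-sample pcor),
#'   \code{boot_mean}, \code{lower}, \code{upper}; failure count in
#'   \code{attr(, "n_failed")}.
#' @export
edge_accuracy <- function(data, control = ggm_control(),
                          boot = boot_config(),
                          method = c("ebic_glasso", "nonreg")) {
  method <- match.arg(method)
  x <- as.matrix(data)
  n <- nrow(x)
  full <- fit_pcor(x, method, control)
  ut <- upper.tri(full)
  draws <- matrix(NA_real_, nrow = boot$n_boot, ncol = sum(ut))
  failed <- 0L
  with_seed(boot$seed, {
    for (b in seq_len(boot$n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      pc <- tryCatch(fit_pcor(x[idx, , drop = FALSE], method, control),
                     error = function(e) NULL)
      if (is.null(pc)) failed <- failed + 1L else draws[b, ] <- pc[ut]
    }
  })
  if (failed > boot$n_boot / 2) {
    stop(sprintf(
      "stability failure: %d of %d bootstrap re-estimations failed",
      failed, boot$n_boot))
  }
  ok <- stats::complete.cases(draws)
  draws <- draws[ok, , drop = FALSE]
  pairs <- which(ut, arr.ind = TRUE)
  items <- rownames(full)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(full)))
  out <- data.frame(
    item_a = items[pairs[, 1]], item_b = items[pairs[, 2]],
    estimate = full[ut],
    boot_mean = colMeans(draws),
    lower = apply(draws, 2L, quantile, probs = 0.025),
    upper = apply(draws, 2L, quantile, probs = 0.975),
    stringsAsFactors = FALSE)
  class(out) <- c("edge_accuracy", "data.frame")
  attr(out, "n_failed") <- failed
  attr(out, "n_boot") <- boot$n_boot
  out
}

# recompute the CS coefficient from stored per-proportion correlations
cs_from_correlations <- function(correlations, cs_correlation,
                                 cs_probability) {
  qualifies <- vapply(correlations, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && mean(v >= cs_correlation) >= cs_probability
  }, logical(1))
  props <- as.numeric(names(correlations))
  if (!any(qualifies)) 0 else max(props[qualifies])
}

#' Case-dropping bootstrap and the CS coefficient
#'
#' For each drop proportion, draws \code{n_boot} row subsamples without
#' replacement of size \code{round((1 - proportion) * n)}, re-estimates
#' strength centrality, and records its Pearson correlation (on raw
#' strengths) with the full-sample strength vector. The correlation-
#' stability (CS) coefficient is the largest proportion whose correlation
#' distribution keeps at least \code{cs_probability} mass at or above
#' \code{cs_correlation}; 0 when no proportion qualifies. Centrality is
#' conventionally considered interpretable when CS exceeds 0.25.
#'
#' Failed re-estimations (and degenerate correlations) are excluded from the
#' distribution and reported, not scored as failures; a proportion whose
#' resamples all fail is marked unusable. If every proportion is unusable
#' the CS coefficient is \code{NA} with diagnostics retained.
#'
#' @inheritParams edge_accuracy
#' @return Object of class \code{"cs_report"}: list with \code{cs}
#'   (the CS coefficient), \code{interpretable}, \code{summary} (per-
#'   proportion data frame with subsample size, number of usable resamples,
#'   correlation quantiles and the qualifying probability), and
#'   \code{correlations} (named list of raw correlation vectors).
#' @export
cs_coefficient <- function(data, control = ggm_control(),
                           boot = boot_config(),
                           method = c("ebic_glasso", "nonreg")) {
  method <- match.arg(method)
  x <- as.matrix(data)
  n <- nrow(x)
  sizes <- as.integer(round((1 - boot$drop_proportions) * n))
  if (min(sizes) < control$min_n) {
    stop(sprintf(
      "largest drop leaves %d rows, below the estimation floor of %d",
      min(sizes), control$min_n))
  }
  full <- fit_pcor(x, method, control)
  s_full <- rowSums(abs(full))
  correlations <- vector("list", length(boot$drop_proportions))
  names(correlations) <- as.character(boot$drop_proportions)
  with_seed(boot$seed, {
    for (d in seq_along(boot$drop_proportions)) {
      m <- sizes[d]
      cors <- rep(NA_real_, boot$n_boot)
      for (b in seq_len(boot$n_boot)) {
        idx <- sample.int(n, m, replace = FALSE)
        pc <- tryCatch(fit_pcor(x[idx, , drop = FALSE], method, control),
                       error = function(e) NULL)
        if (!is.null(pc)) {
          s_sub <- rowSums(abs(pc))
          if (sd(s_sub) > 0 && sd(s_full) > 0) {
            cors[b] <- cor(s_sub, s_full)
          }
        }
      }
      correlations[[d]] <- cors
    }
  })
  usable <- vapply(correlations, function(v) any(!is.na(v)), logical(1))
  qual_prob <- vapply(correlations, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v >= boot$cs_correlation)
  }, numeric(1))
  summary_df <- data.frame(
    drop = boot$drop_proportions,
    size = sizes,
    n_usable = vapply(correlations, function(v) sum(!is.na(v)), integer(1)),
    cor_q05 = vapply(correlations, function(v)
      if (any(!is.na(v))) quantile(v, 0.05, na.rm = TRUE) else NA_real_,
      numeric(1)),
    cor_median = vapply(correlations, function(v)
      if (any(!is.na(v))) stats::median(v, na.rm = TRUE) else NA_real_,
      numeric(1)),
    prob_at_target = qual_prob,
    row.names = NULL)
  cs <- if (!any(usable)) NA_real_ else {
    cs_from_correlations(correlations, boot$cs_correlation,
                         boot$cs_probability)
  }
  structure(list(cs = cs,
                 interpretable = isTRUE(!is.na(cs) && cs > 0.25),
                 cs_correlation = boot$cs_correlation,
                 cs_probability = boot$cs_probability,
                 summary = summary_df,
                 correlations = correlations,
                 method = method, n = n, n_boot = boot$n_boot),
            class = "cs_report")
}

#' @export
print.cs_report <- function(x, ...) {
  cs_txt <- if (is.na(x$cs)) "undefined (no usable drop proportion)"
            else sprintf("%.2f", x$cs)
  cat(sprintf("CS coefficient (cor = %.2f): %s [%s, n = %d, %d resamples]\n",
              x$cs_correlation, cs_txt,
              if (x$interpretable) "interpretable"
              else "not interpretable (<= 0.25)",
              x$n, x$n_boot))
  invisible(x)
}

#' Full stability report: edge accuracy plus centrality stability
#'
#' Convenience wrapper running both [edge_accuracy()] and
#' [cs_coefficient()] under one configuration.
#'
#' @inheritParams edge_accuracy
#' @return Object of class \code{"network_stability"}: list with
#'   \code{edges} (edge-accuracy table) and \code{cs} (CS report).
#' @export
network_stability <- function(data, control = ggm_control(),
                              boot = boot_config(),
                              method = c("ebic_glasso", "nonreg")) {
  method <- match.arg(method)
  structure(list(edges = edge_accuracy(data, control, boot, method),
                 cs = cs_coefficient(data, control, boot, method)),
            class = "network_stability")
}

#' @export
print.network_stability <- function(x, ...) {
  cat(sprintf("Edge-accuracy bootstrap: %d edges, %d resamples (%d failed)\n",
              nrow(x$edges), attr(x$edges, "n_boot"),
              attr(x$edges, "n_failed")))
  print(x$cs)
  invisible(x)
}

#' Write a stability report as JSON
#'
#' @param stability A \code{"network_stability"} or \code{"cs_report"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stability_json <- function(stability, path) {
  payload <- if (inherits(stability, "network_stability")) {
    list(edges = as.data.frame(stability$edges),
         cs_coefficient = stability$cs$cs,
         interpretable = stability$cs$interpretable,
         proportions = stability$cs$summary)
  } else {
    list(cs_coefficient = stability$cs,
         interpretable = stability$interpretable,
         proportions = stability$summary)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
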
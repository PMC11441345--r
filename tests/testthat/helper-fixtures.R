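# Shared fixture builders: all data is generated in code at test time.

# chain-structured partial-correlation matrix (adjacent items connected)
chain_pcor <- function(p, w = 0.3) {
  m <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    m[i, i + 1] <- w
    m[i + 1, i] <- w
  }
  m
}

# latent multivariate-normal draws with a given partial-correlation truth
gaussian_from_pcor <- function(pc, n, seed) {
  K <- pcor_to_precision(pc)
  Sigma <- solve(K)
  set.seed(seed)
  matrix(rnorm(n * ncol(pc)), ncol = ncol(pc)) %*% chol(Sigma)
}

# write a small cohort CSV and return its path
write_cohort_csv <- function(scores, items = paste0("phq", seq_len(ncol(scores))),
                             extra = NULL) {
  df <- as.data.frame(scores)
  names(df) <- items
  if (!is.null(extra)) df <- cbind(df, extra)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# brute-force catalog count independent of the package's enumeration:
# explicit loop over all presence patterns applying the rule definition
brute_force_count <- function(rule) {
  k <- rule$n_items
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  n_present <- rowSums(patterns)
  if (rule$kind == "threshold") {
    sum(n_present * rule$max_item_score >= rule$threshold)
  } else {
    core <- rowSums(patterns[, rule$core_items, drop = FALSE]) > 0
    sum(n_present >= rule$min_count & core)
  }
}
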
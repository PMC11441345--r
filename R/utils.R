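# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic derivation of per-stage seeds from a global seed (Lehmer
# step modulo the Mersenne prime 2^31 - 1, always in [1, 2^31 - 2]).
derive_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483646) + 1
  for (i in seq_len(stage)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# 0/1 vector -> pattern string ("111100000"), item 1 first.
pattern_string <- function(presence) {
  if (is.matrix(presence)) {
    apply(presence, 1L, function(x) paste(as.integer(x), collapse = ""))
  } else {
    paste(as.integer(presence), collapse = "")
  }
}

# pattern string -> integer 0/1 vector
pattern_vector <- function(pattern) {
  x <- as.integer(strsplit(pattern, "")[[1L]])
  if (anyNA(x) || any(x > 1L)) stop("malformed presence pattern: ", pattern)
  x
}

upper_vec <- function(m) m[upper.tri(m)]

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
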
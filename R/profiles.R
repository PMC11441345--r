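#' Exact binomial coefficient
#'
#' Number of ways of selecting \code{r} objects out of \code{n}, evaluated in
#' exact 64-bit integer arithmetic (supported for \code{n <= 64}). Values are
#' returned as doubles, so results above 2^53 are computed exactly but may
#' round on conversion to R's numeric type.
#'
#' @param n,r Non-negative integers with \code{r <= n}.
#' @return The binomial coefficient as a numeric scalar.
#' @examples
#' binomial_exact(9, 4)   # 126
#' @export
binomial_exact <- function(n, r) {
  n <- stopifnot_scalar_count(n, "n", min = 0L)
  r <- stopifnot_scalar_count(r, "r", min = 0L)
  binom_exact_cpp(n, r)
}

#' Diagnostic profile rule
#'
#' Defines which dichotomized symptom profiles are eligible for a diagnosis
#' or inclusion rule. Two rule kinds are supported:
#' \describe{
#'   \item{\code{"threshold"}}{a profile is eligible when its maximum
#'     achievable total score (every present item at \code{max_item_score},
#'     absent items at 0) reaches \code{threshold}. With PHQ-9 defaults
#'     (9 items, max score 3, threshold 10) this yields the 382-profile
#'     catalog of patterns that can score 10 or more.}
#'   \item{\code{"dsm"}}{a DSM-style minimum-count rule: at least
#'     \code{min_count} symptoms present, including at least one of the
#'     \code{core_items} (depressed mood / anhedonia by default); with the
#'     defaults this yields 227 combinations.}
#' }
#'
#' @param kind Rule kind, \code{"threshold"} or \code{"dsm"}.
#' @param n_items Number of items \code{k} (default 9).
#' @param threshold Integer total-score cutoff (threshold rule; default 10).
#' @param max_item_score Maximum per-item score (default 3).
#' @param min_count Minimum number of present symptoms (dsm rule; default 5).
#' @param core_items 1-based indices of the mandatory core symptoms (dsm
#'   rule; default \code{c(1, 2)}).
#' @return An object of class \code{"profile_rule"}.
#' @seealso [enumerate_profiles()], [count_profiles()]
#' @export
profile_rule <- function(kind = c("threshold", "dsm"), n_items = 9L,
                         threshold = 10L, max_item_score = 3L,
                         min_count = 5L, core_items = c(1L, 2L)) {
  kind <- match.arg(kind)
  n_items <- stopifnot_scalar_count(n_items, "n_items")
  threshold <- stopifnot_scalar_count(threshold, "threshold")
  max_item_score <- stopifnot_scalar_count(max_item_score, "max_item_score")
  min_count <- stopifnot_scalar_count(min_count, "min_count")
  core_items <- as.integer(core_items)
  if (kind == "dsm") {
    if (length(core_items) < 1L || anyNA(core_items) ||
        any(core_items < 1L) || any(core_items > n_items)) {
      stop("'core_items' must be item indices in 1..n_items")
    }
  }
  structure(list(kind = kind, n_items = n_items, threshold = threshold,
                 max_item_score = max_item_score, min_count = min_count,
                 core_items = core_items),
            class = "profile_rule")
}

#' @export
print.profile_rule <- function(x, ...) {
  if (x$kind == "threshold") {
    cat(sprintf(
      "Profile rule: threshold (k = %d items scored 0-%d, total >= %d)\n",
      x$n_items, x$max_item_score, x$threshold))
  } else {
    cat(sprintf(
      "Profile rule: dsm (k = %d items, >= %d present incl. core {%s})\n",
      x$n_items, x$min_count, paste(x$core_items, collapse = ",")))
  }
  invisible(x)
}

#' Profile eligibility under a diagnostic rule
#'
#' For a threshold rule a presence/absence pattern is eligible when its
#' maximum achievable total, \code{max_item_score * n_present}, reaches the
#' cutoff; for a dsm rule when at least \code{min_count} symptoms are present
#' including at least one core symptom.
#'
#' @param presence A 0/1 vector of length \code{rule$n_items}, a pattern
#'   string such as \code{"111100000"}, or a matrix with one pattern per row.
#' @param rule A [profile_rule()].
#' @return Logical scalar (or vector for a matrix of patterns).
#' @export
is_eligible <- function(presence, rule) {
  if (is.character(presence)) presence <- pattern_vector(presence)
  if (!is.matrix(presence)) presence <- matrix(presence, nrow = 1L)
  if (ncol(presence) != rule$n_items) {
    stop("presence pattern length does not match rule$n_items")
  }
  if (anyNA(presence) || !all(presence %in% c(0L, 1L))) {
    stop("presence patterns must be 0/1")
  }
  n_present <- rowSums(presence)
  if (rule$kind == "threshold") {
    n_present * rule$max_item_score >= rule$threshold
  } else {
    core <- rowSums(presence[, rule$core_items, drop = FALSE]) > 0
    n_present >= rule$min_count & core
  }
}

#' Enumerate the catalog of eligible symptom profiles
#'
#' Exhaustively enumerates all \code{2^k} dichotomized presence/absence
#' patterns and keeps those eligible under \code{rule}, in canonical order:
#' descending number of present symptoms, then ascending lexicographic order
#' of the pattern string (item 1 most significant). Catalog IDs (1-based)
#' follow that order, so ID 1 is always the all-present profile when it is
#' eligible. The ordering is fully deterministic, giving stable IDs across
#' runs; the sample-dependent frequency ranking is a separate column produced
#' by [profile_frequencies()].
#'
#' @param rule A [profile_rule()]; \code{rule$n_items} must be at most 24 so
#'   that exhaustive enumeration stays tractable.
#' @return An object of class \code{"profile_catalog"}: list with elements
#'   \code{rule}, \code{presence} (catalog-size x k 0/1 matrix),
#'   \code{n_present}, \code{pattern} (strings) and \code{id_of} (named
#'   lookup from pattern string to catalog ID).
#' @examples
#' cat9 <- enumerate_profiles(profile_rule())
#' nrow(cat9$presence)  # 382
#' @export
enumerate_profiles <- function(rule) {
  stopifnot(inherits(rule, "profile_rule"))
  k <- rule$n_items
  if (k > 24L) stop("exhaustive enumeration supported for k <= 24 only")
  codes <- 0:(2^k - 1)
  n_present <- integer(length(codes))
  for (b in 0:(k - 1L)) {
    n_present <- n_present + bitwAnd(bitwShiftR(codes, b), 1L)
  }
  if (rule$kind == "threshold") {
    keep <- n_present * rule$max_item_score >= rule$threshold
  } else {
    # item i occupies bit (k - i) so that item 1 is the most significant bit
    core_mask <- sum(bitwShiftL(1L, k - rule$core_items))
    keep <- n_present >= rule$min_count & bitwAnd(codes, core_mask) > 0L
  }
  codes <- codes[keep]
  n_present <- n_present[keep]
  ord <- order(-n_present, codes)
  codes <- codes[ord]
  n_present <- n_present[ord]
  presence <- matrix(0L, nrow = length(codes), ncol = k)
  for (i in seq_len(k)) {
    presence[, i] <- bitwAnd(bitwShiftR(codes, k - i), 1L)
  }
  pattern <- pattern_string(presence)
  id_of <- seq_along(pattern)
  names(id_of) <- pattern
  structure(list(rule = rule, presence = presence, n_present = n_present,
                 pattern = pattern, id_of = id_of),
            class = "profile_catalog")
}

#' Closed-form catalog size for a threshold rule
#'
#' The number of eligible profiles under a threshold rule equals the sum of
#' binomial coefficients \code{C(k, r)} over symptom counts \code{r} from
#' \code{ceiling(threshold / max_item_score)} to \code{k}; with PHQ-9
#' defaults this is \code{sum(C(9, 4:9)) = 382}.
#'
#' @param rule A threshold-kind [profile_rule()].
#' @return The catalog size as a numeric scalar.
#' @export
count_profiles <- function(rule) {
  stopifnot(inherits(rule, "profile_rule"))
  if (rule$kind != "threshold") {
    stop("closed-form count is defined for threshold rules only")
  }
  r_min <- ceiling(rule$threshold / rule$max_item_score)
  if (r_min > rule$n_items) return(0)
  sum(vapply(r_min:rule$n_items,
             function(r) binomial_exact(rule$n_items, r), numeric(1)))
}

#' Look up catalog IDs for presence patterns
#'
#' @param catalog A [enumerate_profiles()] catalog.
#' @param presence Pattern string(s), a 0/1 vector, or a matrix of patterns.
#' @return Integer catalog IDs; \code{NA} for patterns not in the catalog.
#' @export
profile_id_of <- function(catalog, presence) {
  stopifnot(inherits(catalog, "profile_catalog"))
  if (!is.character(presence)) presence <- pattern_string(presence)
  ids <- unname(catalog$id_of[presence])
  as.integer(ids)
}

#' @export
print.profile_catalog <- function(x, ...) {
  cat(sprintf("Profile catalog: %d eligible profiles over %d items\n",
              length(x$pattern), x$rule$n_items))
  print(x$rule)
  rng <- range(x$n_present)
  cat(sprintf("Symptom counts %d-%d; ID 1 pattern %s\n",
              rng[1], rng[2], x$pattern[1]))
  invisible(x)
}

#' @export
as.data.frame.profile_catalog <- function(x, ...) {
  data.frame(profile_id = seq_along(x$pattern), pattern = x$pattern,
              n_present = x$n_present, stringsAsFactors = FALSE)
}

#' Export a profile catalog as CSV
#'
#' Writes columns \code{profile_id}, \code{pattern} (0/1 string, item 1
#' first) and \code{n_present}, with a header row.
#'
#' @param catalog A profile catalog.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
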
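#' Construct a response matrix from in-memory scores
#'
#' Validates a respondent-by-item matrix of integer item scores and wraps it
#' with per-respondent totals. Rows containing missing or out-of-range values
#' are excluded listwise with a warning (the count is retained in the
#' \code{"n_excluded"} attribute and in pipeline run reports).
#'
#' @param scores Matrix or data frame of integer item scores in
#'   \code{0..max_item_score}, one row per respondent.
#' @param ids Optional respondent identifiers (default \code{R1, R2, ...}).
#' @param max_item_score Maximum valid item score (default 3).
#' @param covariates Optional data frame of per-respondent covariates
#'   (descriptive pass-through only, never used in estimation).
#' @return An object of class \code{"response_matrix"} with elements
#'   \code{scores}, \code{ids}, \code{totals}, \code{included} (NA until
#'   matched), \code{profile_id} (NA until matched), \code{covariates}.
#' @seealso [load_responses()], [match_profiles()]
#' @export
response_matrix <- function(scores, ids = NULL, max_item_score = 3L,
                            covariates = NULL) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("item scores must be numeric")
  if (nrow(scores) == 0L) stop("no respondent rows supplied")
  nonint <- which(!is.na(scores) & scores != floor(scores), arr.ind = TRUE)
  if (nrow(nonint) > 0L) {
    stop(sprintf("non-integer item score at row %d, column %d",
                 nonint[1, 1], nonint[1, 2]))
  }
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(scores)))
  ids <- as.character(ids)
  if (length(ids) != nrow(scores)) stop("ids length must match row count")
  bad <- !complete.cases(scores) |
    apply(scores, 1L, function(x) any(x < 0 | x > max_item_score, na.rm = TRUE))
  if (any(bad)) {
    warning(sprintf(
      "%d respondent row(s) excluded (missing or out-of-range item scores)",
      sum(bad)))
    scores <- scores[!bad, , drop = FALSE]
    ids <- ids[!bad]
    if (!is.null(covariates)) covariates <- covariates[!bad, , drop = FALSE]
    if (nrow(scores) == 0L) stop("no valid respondent rows remain")
  }
  storage.mode(scores) <- "integer"
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  }
  out <- structure(list(scores = scores, ids = ids,
                        totals = as.integer(rowSums(scores)),
                        included = rep(NA, nrow(scores)),
                        profile_id = rep(NA_integer_, nrow(scores)),
                        max_item_score = as.integer(max_item_score),
                        covariates = covariates),
                   class = "response_matrix")
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Read respondent item scores from delimited text
#'
#' Reads a CSV/TSV file with one row per respondent, maps the configured item
#' columns, and validates scores. Rows with missing or out-of-range values
#' are dropped with a warning; non-numeric or non-integer item cells raise a
#' format error naming the column.
#'
#' @param path Path to a delimited text file with a header row.
#' @param items Item column names in instrument order
#'   (default \code{phq1..phq9}).
#' @param id_col Optional respondent-ID column name.
#' @param covariate_cols Optional covariate column names to carry through.
#' @param max_item_score Maximum valid item score (default 3).
#' @param sep Field separator; inferred from the file extension when NULL
#'   (\code{.tsv}/\code{.txt} -> tab, otherwise comma).
#' @return A [response_matrix()].
#' @export
load_responses <- function(path, items = paste0("phq", 1:9), id_col = NULL,
                           covariate_cols = NULL, max_item_score = 3L,
                           sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(raw) == 0L) stop("input file contains a header but no rows")
  missing_cols <- setdiff(c(items, id_col, covariate_cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("unmapped column(s) in input: ", paste(missing_cols, collapse = ", "))
  }
  sc <- raw[, items, drop = FALSE]
  for (cn in items) {
    if (!is.numeric(sc[[cn]])) {
      coerced <- suppressWarnings(as.numeric(sc[[cn]]))
      if (any(is.na(coerced) & !is.na(sc[[cn]]) &
              trimws(sc[[cn]]) != "")) {
        stop(sprintf("non-numeric item score in column '%s'", cn))
      }
      sc[[cn]] <- coerced
    }
  }
  ids <- if (is.null(id_col)) NULL else as.character(raw[[id_col]])
  covs <- if (is.null(covariate_cols)) NULL else
    raw[, covariate_cols, drop = FALSE]
  response_matrix(as.matrix(sc), ids = ids, max_item_score = max_item_score,
                  covariates = covs)
}

#' Dichotomize item scores into a presence/absence profile
#'
#' A symptom is coded present (1) when its item score is 1 or greater and
#' absent (0) when the score is 0.
#'
#' @param scores Integer vector of one respondent's item scores, or a matrix
#'   with one respondent per row.
#' @return 0/1 integer vector (or matrix).
#' @export
dichotomize <- function(scores) {
  if (is.matrix(scores)) {
    out <- (scores >= 1L) + 0L
    dimnames(out) <- dimnames(scores)
    out
  } else {
    as.integer(scores >= 1L)
  }
}

#' Match respondents to catalog profiles
#'
#' Applies the inclusion rule and assigns every included respondent the
#' catalog ID of its dichotomized presence pattern. Under a threshold rule,
#' inclusion means raw total score at or above the threshold (e.g. PHQ-9
#' >= 10); under a dsm rule, inclusion means the dichotomized pattern itself
#' is eligible. Respondents below the bar remain unmatched and excluded.
#'
#' Any included respondent's pattern is mathematically guaranteed to be in a
#' catalog built under the same rule (a raw total of t forces at least
#' \code{ceiling(t / max_item_score)} present symptoms); a missing pattern
#' therefore signals a rule/catalog configuration mismatch and raises an
#' error.
#'
#' @param responses A [response_matrix()].
#' @param catalog A [enumerate_profiles()] catalog built under the same rule.
#' @return The response matrix with \code{included} and \code{profile_id}
#'   filled in.
#' @export
match_profiles <- function(responses, catalog) {
  stopifnot(inherits(responses, "response_matrix"),
            inherits(catalog, "profile_catalog"))
  rule <- catalog$rule
  if (ncol(responses$scores) != rule$n_items) {
    stop("response item count does not match catalog rule")
  }
  pres <- dichotomize(responses$scores)
  if (rule$kind == "threshold") {
    included <- responses$totals >= rule$threshold
  } else {
    included <- as.logical(is_eligible(pres, rule))
  }
  ids <- rep(NA_integer_, length(included))
  if (any(included)) {
    ids[included] <- profile_id_of(catalog, pres[included, , drop = FALSE])
    if (anyNA(ids[included])) {
      stop("included respondent pattern missing from catalog; ",
           "catalog was built under a different rule than the inclusion rule")
    }
  }
  responses$included <- included
  responses$profile_id <- ids
  responses
}

#' PHQ-9 severity band of a total score
#'
#' Convenience banding following the source instrument's published severity
#' labels for clinically significant scores: "moderate" for totals of 14 or
#' below, "moderately severe" for 15-19, "severe" for 20 and above.
#' Totals below the clinical threshold are labelled "subthreshold".
#'
#' @param total Integer total score(s).
#' @param threshold Clinical threshold (default 10).
#' @return Character vector of band labels.
#' @export
severity_band <- function(total, threshold = 10L) {
  out <- ifelse(total < threshold, "subthreshold",
         ifelse(total <= 14L, "moderate",
         ifelse(total <= 19L, "moderately severe", "severe")))
  out
}

#' Profile frequency and descriptives table
#'
#' One row per catalog profile observed in the included sample, ranked by
#' frequency (ties broken by ascending catalog ID), with percent of the
#' included sample, cumulative percent, and per-profile mean/SD of the total
#' score. Numeric covariates supplied at construction contribute per-profile
#' means.
#'
#' @param responses A matched [response_matrix()].
#' @param catalog The catalog used for matching.
#' @return A data frame of class \code{"profile_frequencies"} with columns
#'   \code{rank}, \code{profile_id}, \code{pattern}, \code{n_present},
#'   \code{n}, \code{percent}, \code{cum_percent}, \code{mean_total},
#'   \code{sd_total}, plus \code{mean_<covariate>} columns.
#' @export
profile_frequencies <- function(responses, catalog) {
  stopifnot(inherits(responses, "response_matrix"),
            inherits(catalog, "profile_catalog"))
  if (all(is.na(responses$included))) {
    stop("responses have not been matched; call match_profiles() first")
  }
  inc <- which(responses$included %in% TRUE)
  if (length(inc) == 0L) {
    warning("no respondents meet the inclusion rule; returning empty table")
    out <- data.frame(rank = integer(), profile_id = integer(),
                      pattern = character(), n_present = integer(),
                      n = integer(), percent = numeric(),
                      cum_percent = numeric(), mean_total = numeric(),
                      sd_total = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("profile_frequencies", "data.frame")
    attr(out, "n_included") <- 0L
    return(out)
  }
  pid <- responses$profile_id[inc]
  totals <- responses$totals[inc]
  counts <- table(pid)
  ids <- as.integer(names(counts))
  n <- as.integer(counts)
  ord <- order(-n, ids)
  ids <- ids[ord]
  n <- n[ord]
  percent <- 100 * n / length(inc)
  out <- data.frame(
    rank = seq_along(ids),
    profile_id = ids,
    pattern = catalog$pattern[ids],
    n_present = catalog$n_present[ids],
    n = n,
    percent = percent,
    cum_percent = cumsum(percent),
    mean_total = vapply(ids, function(i) mean(totals[pid == i]), numeric(1)),
    sd_total = vapply(ids, function(i) sd(totals[pid == i]), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(responses$covariates)) {
    covs <- responses$covariates[inc, , drop = FALSE]
    for (cn in names(covs)) {
      if (is.numeric(covs[[cn]])) {
        out[[paste0("mean_", cn)]] <- vapply(
          ids, function(i) mean(covs[[cn]][pid == i], na.rm = TRUE),
          numeric(1))
      }
    }
  }
  class(out) <- c("profile_frequencies", "data.frame")
  attr(out, "n_included") <- length(inc)
  out
}

#' @export
print.profile_frequencies <- function(x, max_rows = 10L, ...) {
  cat(sprintf("Profile frequencies: %d distinct profiles, %d respondents\n",
              nrow(x), attr(x, "n_included")))
  if (nrow(x) > 0L) {
    show <- utils::head(as.data.frame(x), max_rows)
    show$percent <- round(show$percent, 1)
    show$cum_percent <- round(show$cum_percent, 1)
    show$mean_total <- round(show$mean_total, 2)
    show$sd_total <- round(show$sd_total, 2)
    print(show, row.names = FALSE)
    if (nrow(x) > max_rows) cat(sprintf("... %d more rows\n",
                                        nrow(x) - max_rows))
  }
  invisible(x)
}

#' Coverage of the top-ranked profiles
#'
#' Percent of the included sample represented by the \code{top_m} most
#' frequent profiles (the "q% of cases are covered by m profiles" statistic).
#'
#' @param freq A [profile_frequencies()] table.
#' @param top_m Number of top-ranked profiles (>= 1).
#' @return Percent coverage as a numeric scalar.
#' @export
coverage <- function(freq, top_m) {
  stopifnot(inherits(freq, "profile_frequencies"))
  top_m <- stopifnot_scalar_count(top_m, "top_m")
  if (nrow(freq) == 0L) return(0)
  if (top_m >= nrow(freq)) {
    if (top_m > nrow(freq)) {
      warning("top_m exceeds the number of observed profiles; returning 100%")
    }
    return(sum(freq$percent))
  }
  sum(freq$percent[seq_len(top_m)])
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d respondents x %d items (scores 0-%d)\n",
              nrow(x$scores), ncol(x$scores), x$max_item_score))
  if (!all(is.na(x$included))) {
    cat(sprintf("Matched: %d included, %d excluded by the inclusion rule\n",
                sum(x$included, na.rm = TRUE),
                sum(!x$included, na.rm = TRUE)))
  }
  invisible(x)
}

#' Export a (matched) response matrix as CSV
#'
#' Writes one row per respondent with id, item scores, total, and (when
#' matched) inclusion flag and catalog profile ID. [read_responses_csv()]
#' restores the object, round-tripping scores, inclusion and matched IDs.
#'
#' @param responses A [response_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(id = responses$ids, responses$scores,
                   total = responses$totals,
                   included = responses$included,
                   profile_id = responses$profile_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(responses$covariates)) df <- cbind(df, responses$covariates)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Re-import a response matrix written by [write_responses()]
#'
#' @param path CSV path written by [write_responses()].
#' @param items Item column names (default: columns between \code{id} and
#'   \code{total}).
#' @param max_item_score Maximum valid item score.
#' @return A [response_matrix()] with inclusion flags and profile IDs
#'   restored.
#' @export
read_responses_csv <- function(path, items = NULL, max_item_score = 3L) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(items)) {
    stopifnot("id" %in% names(raw), "total" %in% names(raw))
    items <- names(raw)[(which(names(raw) == "id") + 1L):
                        (which(names(raw) == "total") - 1L)]
  }
  covs <- setdiff(names(raw), c("id", items, "total", "included",
                                "profile_id"))
  rm_ <- response_matrix(as.matrix(raw[, items, drop = FALSE]),
                         ids = raw$id, max_item_score = max_item_score,
                         covariates = if (length(covs)) {
                           raw[, covs, drop = FALSE]
                         } else NULL)
  if ("included" %in% names(raw)) rm_$included <- as.logical(raw$included)
  if ("profile_id" %in% names(raw)) rm_$profile_id <-
      as.integer(raw$profile_id)
  rm_
}
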
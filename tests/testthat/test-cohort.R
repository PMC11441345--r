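test_that("loading validates, maps and filters respondent rows", {
  sc <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1, 2),
              c(0, 0, 0, 0, 0, 0, 0, 0, 0),
              c(3, 2, 1, 3, 0, 0, 0, 0, 0))
  path <- write_cohort_csv(sc)
  rm_ <- load_responses(path)
  expect_s3_class(rm_, "response_matrix")
  expect_equal(nrow(rm_$scores), 3)
  expect_equal(rm_$totals, c(10L, 0L, 9L))

  # out-of-range value drops the row with a warning
  sc_bad <- rbind(sc, c(4, rep(0, 8)))
  expect_warning(rm2 <- load_responses(write_cohort_csv(sc_bad)),
                 "excluded")
  expect_equal(nrow(rm2$scores), 3)
  expect_equal(attr(rm2, "n_excluded"), 1L)

  # header-only file is a hard error
  empty <- tempfile(fileext = ".csv")
  writeLines(paste(paste0("phq", 1:9), collapse = ","), empty)
  expect_error(load_responses(empty), "no rows")

  # non-numeric cells name the offending column
  txt <- tempfile(fileext = ".csv")
  writeLines(c(paste(paste0("phq", 1:9), collapse = ","),
               paste(c("abc", rep("1", 8)), collapse = ",")), txt)
  expect_error(load_responses(txt), "phq1")

  # unmapped columns are reported
  expect_error(load_responses(path, items = paste0("q", 1:9)), "unmapped")

  # non-integer score is a format error with row/column position
  expect_error(response_matrix(rbind(c(1.5, rep(0, 8)))), "row 1, column 1")
})

test_that("dichotomization codes presence at score >= 1", {
  expect_identical(dichotomize(c(1, 1, 1, 1, 1, 1, 1, 1, 2)), rep(1L, 9))
  expect_identical(dichotomize(rep(0, 9)), rep(0L, 9))
  expect_identical(dichotomize(c(3, 2, 1, 3, 0, 0, 0, 0, 0)),
                   c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("matching assigns catalog IDs above threshold only", {
  cat9 <- enumerate_profiles(profile_rule())
  sc <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1, 2),   # total 10, all present
              c(3, 3, 3, 0, 0, 0, 0, 0, 0),   # total 9, excluded
              c(3, 3, 3, 1, 0, 0, 0, 0, 0))   # total 10, items 1-4
  m <- match_profiles(response_matrix(sc), cat9)
  expect_identical(m$included, c(TRUE, FALSE, TRUE))
  expect_identical(m$profile_id[1], 1L)
  expect_true(is.na(m$profile_id[2]))
  expect_identical(cat9$pattern[m$profile_id[3]], "111100000")
})

test_that("every included respondent gets exactly one in-catalog ID", {
  cat9 <- enumerate_profiles(profile_rule())
  set.seed(7)
  for (rep in 1:5) {
    sc <- matrix(sample(0:3, 9 * 200, replace = TRUE), ncol = 9)
    m <- match_profiles(response_matrix(sc), cat9)
    inc <- m$included
    expect_true(all(!is.na(m$profile_id[inc])))
    expect_true(all(is.na(m$profile_id[!inc])))
    # total >= 10 at max score 3 forces >= 4 present symptoms
    expect_true(all(rowSums(dichotomize(sc[inc, , drop = FALSE])) >= 4))
  }
})

test_that("frequency table ranks, percents and coverage behave", {
  cat9 <- enumerate_profiles(profile_rule())

  # degenerate single-pattern cohort
  sc <- matrix(2L, nrow = 12, ncol = 9)
  m <- match_profiles(response_matrix(sc), cat9)
  ft <- profile_frequencies(m, cat9)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$percent, 100)
  expect_equal(coverage(ft, 1), 100)

  # planted mixture 0.5/0.3/0.2 recovers the weights within 3 points
  spec <- synthetic_spec(1000, list(
    subpopulation(rep(1, 9), weight = 0.5),
    subpopulation(c(rep(1, 8), 0), weight = 0.3),
    subpopulation(c(rep(1, 7), 0, 0), weight = 0.2)), seed = 123)
  mm <- match_profiles(sample_cohort(spec), cat9)
  ft2 <- profile_frequencies(mm, cat9)
  expect_equal(nrow(ft2), 3)
  expect_true(all(abs(ft2$percent - c(50, 30, 20)) < 3))
  expect_true(abs(coverage(ft2, 2) - 80) < 3)
  expect_equal(coverage(ft2, 3), 100)
  expect_warning(cov_all <- coverage(ft2, 10), "exceeds")
  expect_equal(cov_all, 100)

  # equal counts rank by ascending catalog ID
  sc3 <- rbind(matrix(2L, 5, 9),
               matrix(rep(c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 0L), 5),
                      5, 9, byrow = TRUE))
  ft3 <- profile_frequencies(match_profiles(response_matrix(sc3), cat9), cat9)
  expect_equal(ft3$profile_id, sort(ft3$profile_id))

  # percents are invariant to respondent order
  perm <- sample(nrow(sc3))
  ft4 <- profile_frequencies(match_profiles(response_matrix(sc3[perm, ]),
                                            cat9), cat9)
  expect_equal(ft3$percent, ft4$percent)

  # empty cohort yields an empty table with a warning, not an error
  low <- match_profiles(response_matrix(matrix(0L, 3, 9)), cat9)
  expect_warning(ft5 <- profile_frequencies(low, cat9), "no respondents")
  expect_equal(nrow(ft5), 0)
})

test_that("severity bands follow the instrument's published labels", {
  expect_identical(severity_band(c(5, 10, 14, 15, 19, 20, 27)),
                   c("subthreshold", "moderate", "moderate",
                     "moderately severe", "moderately severe",
                     "severe", "severe"))
})

test_that("matched cohorts round-trip through CSV", {
  cat9 <- enumerate_profiles(profile_rule())
  set.seed(11)
  sc <- matrix(sample(0:3, 9 * 50, replace = TRUE), ncol = 9,
               dimnames = list(NULL, paste0("phq", 1:9)))
  m <- match_profiles(response_matrix(sc, covariates = data.frame(
    age = sample(18:90, 50, replace = TRUE))), cat9)
  path <- tempfile(fileext = ".csv")
  write_responses(m, path)
  back <- read_responses_csv(path)
  expect_equal(unname(back$scores), unname(m$scores))
  expect_identical(back$included, m$included)
  expect_identical(back$profile_id, m$profile_id)
  expect_equal(back$covariates$age, m$covariates$age)
})

test_that("covariates contribute per-profile means only", {
  cat9 <- enumerate_profiles(profile_rule())
  sc <- matrix(2L, nrow = 10, ncol = 9)
  age <- c(rep(30, 5), rep(50, 5))
  m <- match_profiles(response_matrix(sc, covariates = data.frame(age = age)),
                      cat9)
  ft <- profile_frequencies(m, cat9)
  expect_equal(ft$mean_age, 40)
  expect_equal(ft$mean_total, 18)
  expect_equal(ft$sd_total, 0)
})
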
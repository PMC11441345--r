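test_that("pcor-to-precision validates and inverts the edge transform", {
  expect_equal(pcor_to_precision(matrix(0, 3, 3)), diag(3))
  pc <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  K <- pcor_to_precision(pc)
  expect_equal(K[1, 2], -0.5)
  expect_equal(diag(K), c(1, 1))
  # an inconsistent specification is rejected
  bad <- matrix(0.8, 3, 3); diag(bad) <- 0
  expect_error(pcor_to_precision(bad), "positive definite")
  expect_error(pcor_to_precision(matrix(c(0, 1, 1, 0), 2, 2)),
               "strictly inside")
})

test_that("generated respondents carry their planted profile exactly", {
  profile <- c(rep(1, 8), 0)
  spec <- synthetic_spec(500, subpopulation(profile,
                                            pcor = chain_pcor(8, 0.25)),
                         seed = 15)
  co <- sample_cohort(spec)
  d <- dichotomize(co$scores)
  expect_true(all(t(d) == as.integer(profile)))
  expect_true(all(co$scores[, 9] == 0))
  expect_true(all(co$scores[, 1:8] >= 1))
  # all-present planted profiles always total at least k
  spec9 <- synthetic_spec(200, subpopulation(rep(1, 9)), seed = 16)
  expect_true(all(sample_cohort(spec9)$totals >= 9))
})

test_that("the generator is deterministic given its spec", {
  spec <- synthetic_spec(200, list(
    subpopulation(rep(1, 9), weight = 0.6, pcor = chain_pcor(9, 0.2)),
    subpopulation(c(rep(1, 7), 0, 0), weight = 0.4)), seed = 99)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1$scores, c2$scores)
  expect_identical(attr(c1, "planted"), attr(c2, "planted"))
  # and writes byte-identical cohort files
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_responses(c1, p1); write_responses(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mixture weights surface as frequency ranks", {
  cat9 <- enumerate_profiles(profile_rule())
  spec <- synthetic_spec(1000, list(
    subpopulation(rep(1, 9), weight = 0.5),
    subpopulation(c(rep(1, 8), 0), weight = 0.3),
    subpopulation(c(rep(1, 7), 0, 0), weight = 0.2)), seed = 31)
  ft <- profile_frequencies(match_profiles(sample_cohort(spec), cat9), cat9)
  expect_identical(ft$pattern[1:3],
                   c("111111111", "111111110", "111111100"))
})

test_that("the independence ground truth is recovered at large n", {
  spec <- synthetic_spec(10000, subpopulation(rep(1, 9)), seed = 8)
  rec <- recovery_experiment(spec)
  expect_true(all(abs(coef(rec$network)) < 0.05))
  expect_error(recovery_experiment(synthetic_spec(100, list(
    subpopulation(rep(1, 9), weight = 0.5),
    subpopulation(rep(1, 9), weight = 0.5)), seed = 1)),
    "single-subpopulation")
})

test_that("planted networks are recovered from ordinal cohorts", {
  pc <- random_sparse_pcor(9, 8, c(0.25, 0.35), seed = 11)
  spec <- synthetic_spec(2000, subpopulation(rep(1, 9), pcor = pc),
                         seed = 11)
  rec <- recovery_experiment(spec)
  expect_gte(rec$edge_correlation, 0.7)
  expect_gte(rec$specificity, 0.9)
  expect_gte(rec$sensitivity, 0.9)
})

test_that("the analytic inclusion rate matches the empirical pass rate", {
  profile <- c(rep(1, 6), 0, 0, 0)
  spec <- synthetic_spec(5000, subpopulation(profile), seed = 21)
  expected <- inclusion_rate(spec, threshold = 10)
  observed <- mean(sample_cohort(spec)$totals >= 10)
  expect_lt(abs(expected - observed), 0.03)
  # boundary checks: all-present profiles with max scores always pass
  expect_equal(inclusion_rate(synthetic_spec(
    10, subpopulation(rep(1, 9)), seed = 1), threshold = 9), 1)
})

test_that("YAML specs and truth tables round-trip", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_respondents: 150",
    "seed: 4",
    "subpopulations:",
    "  - profile: '111110000'",
    "    weight: 0.7",
    "    edges:",
    "      - [1, 2, 0.3]",
    "      - [2, 3, 0.2]",
    "  - profile: '111111111'",
    "    weight: 0.3"), path)
  spec <- read_spec_yaml(path)
  expect_equal(spec$n, 150L)
  expect_equal(length(spec$subpops), 2)
  expect_equal(spec$subpops[[1]]$pcor[1, 2], 0.3)
  expect_equal(spec$weights, c(0.7, 0.3))
  tpath <- tempfile(fileext = ".csv")
  write_truth(spec, tpath)
  truth <- read.csv(tpath)
  expect_equal(nrow(truth), 2)
  expect_equal(truth$pcor, c(0.3, 0.2))
  expect_identical(truth$item_a, c("phq1", "phq2"))
  # the spec is usable end to end
  co <- sample_cohort(spec)
  expect_equal(nrow(co$scores), 150)
})
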
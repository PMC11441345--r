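test_that("binomial coefficients are exact and validate their inputs", {
  expect_identical(binomial_exact(9, 4), 126)
  expect_identical(binomial_exact(9, 0), 1)
  expect_identical(binomial_exact(9, 9), 1)
  # against base R for sizes where doubles are exact
  set.seed(1)
  for (i in 1:50) {
    n <- sample(0:52, 1)
    r <- if (n == 0) 0 else sample(0:n, 1)
    expect_equal(binomial_exact(n, r), choose(n, r))
  }
  expect_error(binomial_exact(4, 5), "r must not exceed n|>=")
  expect_error(binomial_exact(-1, 0))
  expect_error(binomial_exact(3, -2))
})

test_that("threshold eligibility is maximum-achievable-total >= cutoff", {
  rule <- profile_rule()  # 9 items, max 3, threshold 10
  four <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_true(is_eligible(four, rule))          # 4 x 3 = 12 >= 10
  expect_false(is_eligible(c(1, 1, 1, 0, 0, 0, 0, 0, 0), rule))  # 9 < 10
  expect_false(is_eligible(rep(0, 9), rule))
  expect_false(is_eligible(rep(0, 9), profile_rule("dsm")))
  # dsm: >= 5 present including a core symptom
  dsm <- profile_rule("dsm")
  expect_true(is_eligible(c(1, 0, 1, 1, 1, 1, 0, 0, 0), dsm))
  expect_false(is_eligible(c(0, 0, 1, 1, 1, 1, 1, 0, 0), dsm))  # no core
  expect_false(is_eligible(c(1, 1, 1, 1, 0, 0, 0, 0, 0), dsm))  # only 4
  expect_error(is_eligible(c(1, 0), rule), "length")
})

test_that("catalog enumeration reproduces the printed catalog sizes", {
  cat9 <- enumerate_profiles(profile_rule())
  expect_equal(length(cat9$pattern), 382)
  expect_equal(count_profiles(profile_rule()), 382)
  expect_equal(length(enumerate_profiles(profile_rule("dsm"))$pattern), 227)
  expect_equal(length(enumerate_profiles(
    profile_rule(threshold = 27))$pattern), 1)
  expect_equal(count_profiles(profile_rule(threshold = 1)), 511)
  expect_equal(count_profiles(profile_rule(n_items = 4, threshold = 10)), 1)
})

test_that("catalog ordering is canonical, deterministic and indexed", {
  cat9 <- enumerate_profiles(profile_rule())
  # descending symptom count, ID 1 = all-present
  expect_identical(cat9$pattern[1], "111111111")
  expect_true(all(diff(cat9$n_present) <= 0))
  # lexicographic within a count stratum (item 1 most significant)
  r8 <- cat9$pattern[cat9$n_present == 8]
  expect_identical(r8, sort(r8))
  # stable across runs
  expect_identical(cat9$pattern, enumerate_profiles(profile_rule())$pattern)
  # id_of is a bijection consistent with position
  expect_identical(profile_id_of(cat9, cat9$pattern), seq_along(cat9$pattern))
  expect_identical(profile_id_of(cat9, "111111111"), 1L)
  expect_true(is.na(profile_id_of(cat9, "100000000")))
  # profiles are distinct
  expect_false(anyDuplicated(cat9$pattern) > 0)
})

test_that("closed form agrees with brute force over randomized rules", {
  set.seed(42)
  for (i in 1:40) {
    k <- sample(2:12, 1)
    ms <- sample(1:4, 1)
    thr <- sample(1:(k * ms), 1)
    rule <- profile_rule(n_items = k, max_item_score = ms, threshold = thr)
    cf <- count_profiles(rule)
    expect_equal(cf, brute_force_count(rule))
    expect_equal(cf, length(enumerate_profiles(rule)$pattern))
  }
  # dsm rules against brute force too
  for (i in 1:10) {
    k <- sample(3:10, 1)
    rule <- profile_rule("dsm", n_items = k,
                         min_count = sample(1:k, 1),
                         core_items = sample(seq_len(k), sample(1:2, 1)))
    expect_equal(length(enumerate_profiles(rule)$pattern),
                 brute_force_count(rule))
  }
})

test_that("raising the threshold never enlarges the catalog", {
  sizes <- vapply(1:27, function(thr) {
    length(enumerate_profiles(profile_rule(threshold = thr))$pattern)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("catalog CSV export round-trips", {
  cat9 <- enumerate_profiles(profile_rule())
  path <- tempfile(fileext = ".csv")
  write_catalog(cat9, path)
  back <- read.csv(path, colClasses = c(pattern = "character"))
  expect_equal(nrow(back), 382)
  expect_identical(names(back), c("profile_id", "pattern", "n_present"))
  expect_identical(back$pattern, cat9$pattern)
  expect_equal(back$n_present, cat9$n_present)
})
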
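test_that("sample correlations detect collinearity and degeneracy", {
  set.seed(3)
  a <- rnorm(100)
  S <- sample_correlation(cbind(a, 2 * a + 1, rnorm(100)))
  expect_equal(S[1, 2], 1)
  expect_error(sample_correlation(cbind(a, rep(2, 100))), "degenerate")
  # independent noise concentrates near zero at large n
  x <- matrix(rnorm(10000 * 4), ncol = 4)
  S2 <- sample_correlation(x)
  expect_true(max(abs(S2[upper.tri(S2)])) < 0.05)
})

test_that("the penalty path starts empty and handles independence", {
  set.seed(4)
  x <- matrix(rnorm(500 * 3), ncol = 3)
  S <- sample_correlation(x)
  path <- glasso_path(S, 500)
  # at lambda_max the solution is diagonal: E = 0 and EBIC = -2 loglik
  expect_equal(path$edges[1], 0)
  expect_equal(path$ebic[1], -2 * path$loglik[1])
  K1 <- path$precision[, , 1]
  expect_equal(K1[upper.tri(K1)], rep(0, 3))
  # exact identity input stays diagonal at every penalty
  pI <- glasso_path(diag(3), 500)
  expect_true(all(pI$edges == 0))
  expect_error(glasso_path(S, 3), "sample size")
})

test_that("edge count grows as the penalty shrinks (statistically)", {
  monotone <- 0
  for (s in 1:20) {
    pc <- random_sparse_pcor(5, 4, c(0.2, 0.4), seed = s)
    x <- gaussian_from_pcor(pc, 300, seed = 100 + s)
    path <- glasso_path(sample_correlation(x), 300)
    monotone <- monotone + all(diff(path$edges) >= 0)
  }
  expect_gte(monotone, 19)
})

test_that("EBIC selection matches the exhaustive-support oracle", {
  # single strong pair among 3 items: exactly that edge is selected
  pc <- matrix(0, 3, 3)
  pc[1, 2] <- pc[2, 1] <- 0.6
  x <- gaussian_from_pcor(pc, 500, seed = 21)
  S <- sample_correlation(x)
  net <- select_ebic(glasso_path(S, 500))
  sel <- coef(net) != 0
  expect_identical(unname(sel[upper.tri(sel)]), c(TRUE, FALSE, FALSE))
  oracle <- support_search(S, 500)
  expect_equal(unname(sel[upper.tri(sel)]),
               unname(oracle$support[upper.tri(oracle$support)]))
  # small-p oracle agreement across seeds
  agree <- 0
  for (s in 1:5) {
    pcs <- random_sparse_pcor(3, 1, c(0.3, 0.4), seed = s)
    xs <- gaussian_from_pcor(pcs, 1000, seed = 200 + s)
    Ss <- sample_correlation(xs)
    nets <- select_ebic(glasso_path(Ss, 1000))
    os <- support_search(Ss, 1000)
    agree <- agree + all((coef(nets) != 0)[upper.tri(Ss)] ==
                           os$support[upper.tri(Ss)])
  }
  expect_gte(agree, 4)
})

test_that("precision-to-pcor conversion flips sign and keeps zeros", {
  K <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  pc <- precision_to_pcor(K)
  expect_equal(pc[1, 2], 0.5)
  expect_equal(diag(pc), c(0, 0))
  # diagonal precision -> all-zero pcor
  expect_equal(precision_to_pcor(diag(3)), matrix(0, 3, 3))
  # round trip with the synthetic-data transform
  pc3 <- chain_pcor(4, 0.3)
  expect_equal(precision_to_pcor(pcor_to_precision(pc3)), pc3)
})

test_that("fitted networks satisfy their structural invariants", {
  for (s in 1:5) {
    pc <- random_sparse_pcor(6, 5, c(0.2, 0.35), seed = s)
    x <- gaussian_from_pcor(pc, 400, seed = 300 + s)
    net <- symptom_network(x)
    w <- coef(net)
    expect_equal(w, t(w))
    expect_true(all(abs(w) <= 1))
    expect_equal(unname(diag(w)), rep(0, 6))
  }
})

test_that("the non-regularized estimator thresholds by Fisher z", {
  # alpha = 1 reproduces the inversion partial correlations exactly
  pc <- chain_pcor(4, 0.3)
  x <- gaussian_from_pcor(pc, 500, seed = 31)
  S <- sample_correlation(x)
  net1 <- symptom_network(x, method = "nonreg",
                          control = ggm_control(alpha = 1))
  K <- solve(S)
  pfull <- -K / sqrt(outer(diag(K), diag(K)))
  diag(pfull) <- 0
  expect_lt(max(abs(coef(net1) - pfull)), 1e-10)

  # a planted 0.4 edge is retained at n = 300
  pc2 <- matrix(0, 3, 3)
  pc2[1, 2] <- pc2[2, 1] <- 0.4
  net2 <- symptom_network(gaussian_from_pcor(pc2, 300, seed = 5),
                          method = "nonreg")
  expect_gt(abs(coef(net2)[1, 2]), 0)

  # singular correlation matrix advises the regularized method
  a <- rnorm(50)
  expect_error(
    suppressWarnings(symptom_network(cbind(a, a, rnorm(50)),
                                     method = "nonreg")),
    "singular|degenerate")
})

test_that("nonreg false-positive rate tracks alpha under the null", {
  set.seed(99)
  fp <- replicate(400, {
    x <- matrix(rnorm(120 * 4), ncol = 4)
    w <- coef(suppressWarnings(symptom_network(x, method = "nonreg")))
    mean(w[upper.tri(w)] != 0)
  })
  expect_gt(mean(fp), 0.03)
  expect_lt(mean(fp), 0.07)
})

test_that("strength centrality sums absolute incident weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[1, 3] <- w[3, 1] <- -0.2
  w[2, 3] <- w[3, 2] <- 0.1
  cent <- strength_centrality(w)
  expect_equal(cent$strength, c(0.5, 0.4, 0.3))
  expect_equal(cent$rank, c(1L, 2L, 3L))
  # all-equal edges: tied strengths ranked by item order
  weq <- matrix(0.2, 3, 3); diag(weq) <- 0
  ceq <- strength_centrality(weq)
  expect_equal(ceq$strength, rep(0.4, 3))
  expect_equal(ceq$rank, 1:3)
  expect_true(attr(ceq, "degenerate"))
  expect_true(all(is.na(ceq$z_strength)))
  # empty network: zero strengths flagged degenerate
  c0 <- strength_centrality(matrix(0, 4, 4))
  expect_equal(c0$strength, rep(0, 4))
  expect_true(attr(c0, "degenerate"))
  # z-scores standardized when non-degenerate
  expect_equal(mean(cent$z_strength), 0)
  expect_equal(sd(cent$z_strength), 1)
})

test_that("strength is invariant under item permutation", {
  pc <- random_sparse_pcor(5, 4, c(0.2, 0.4), seed = 9)
  rownames(pc) <- colnames(pc) <- paste0("v", 1:5)
  s1 <- strength_centrality(pc)
  perm <- c(3, 1, 5, 2, 4)
  s2 <- strength_centrality(pc[perm, perm])
  expect_equal(s2$strength[match(s1$item, s2$item)], s1$strength)
})

test_that("layouts are deterministic, bounded and symmetric", {
  pc <- chain_pcor(4, 0.3)
  x <- gaussian_from_pcor(pc, 300, seed = 13)
  net <- symptom_network(x)
  l1 <- network_layout(net, seed = 7)
  l2 <- network_layout(net, seed = 7)
  expect_identical(l1, l2)
  expect_true(all(l1$x >= 0 & l1$x <= 1 & l1$y >= 0 & l1$y <= 1))
  # two connected nodes sit symmetric about the center after rescaling
  two <- structure(list(items = c("a", "b"),
                        pcor = matrix(c(0, 0.4, 0.4, 0), 2, 2),
                        method = "nonreg", n = 100),
                   class = "symptom_network")
  lt <- network_layout(two, seed = 1)
  expect_equal(mean(lt$x), 0.5)
  expect_equal(mean(lt$y), 0.5)
  # single node is centered
  one <- structure(list(items = "a", pcor = matrix(0, 1, 1),
                        method = "nonreg", n = 100),
                   class = "symptom_network")
  expect_equal(network_layout(one)[, c("x", "y")],
               data.frame(x = 0.5, y = 0.5))
})

test_that("profile subsamples drop absent items and enforce the floor", {
  cat9 <- enumerate_profiles(profile_rule())
  spec <- synthetic_spec(300, list(
    subpopulation(rep(1, 9), weight = 0.6),
    subpopulation(c(rep(1, 8), 0), weight = 0.4)), seed = 77)
  m <- match_profiles(sample_cohort(spec), cat9)
  full <- profile_subsample(m, cat9, 1L)
  expect_equal(ncol(full), 9)
  expect_length(attr(full, "dropped_items"), 0)
  pid8 <- profile_id_of(cat9, "111111110")
  sub8 <- profile_subsample(m, cat9, pid8)
  expect_equal(ncol(sub8), 8)
  expect_identical(attr(sub8, "dropped_items"), "phq9")
  expect_true(all(sub8 >= 1))
  expect_error(profile_subsample(m, cat9, pid8, min_n = 10000),
               "below the estimation floor")
})

test_that("small samples are refused or warned about", {
  x <- matrix(rnorm(5 * 3), ncol = 3)
  expect_error(symptom_network(x), "below the estimation floor")
  x2 <- matrix(rnorm(40 * 3), ncol = 3)
  expect_warning(symptom_network(x2), "small")
})

test_that("simulation from a fitted network is seeded and shaped", {
  pc <- chain_pcor(3, 0.3)
  net <- symptom_network(gaussian_from_pcor(pc, 400, seed = 17))
  y1 <- simulate(net, nsim = 50, seed = 3)
  y2 <- simulate(net, nsim = 50, seed = 3)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(50, 3))
  expect_identical(colnames(y1), net$items)
})
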
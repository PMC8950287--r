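test_that("patefield samples preserve marginals exactly", {
  set.seed(2)
  for (i in 1:25) {
    r <- rpois(sample(2:5, 1), 4) + 1L
    cs <- as.integer(rmultinom(1, sum(r), rep(1, sample(2:5, 1))))
    if (any(cs == 0)) cs[cs == 0] <- cs[cs == 0] + 0L  # zeros allowed
    tab <- patefield_sample(r, cs)
    expect_equal(rowSums(tab), as.numeric(r))
    expect_equal(colSums(tab), as.numeric(cs))
  }
  expect_error(patefield_sample(c(2, 1), c(1, 1)), "equal sums")
})

test_that("2x2 symmetry: unit marginals give each table half the time", {
  set.seed(8)
  hits <- replicate(10000, patefield_sample(c(1, 1), c(1, 1))[1, 1])
  # binomial(10000, 1/2): 3 sigma band is +-150
  expect_lt(abs(mean(hits) - 0.5), 0.015)
})

test_that("cell means match the hypergeometric expectation r_i c_j / F", {
  set.seed(13)
  r <- c(6, 3, 1)
  cs <- c(4, 4, 2)
  n <- 20000
  acc <- matrix(0, 3, 3)
  for (k in seq_len(n)) acc <- acc + patefield_sample(r, cs)
  expect_lt(max(abs(acc / n - outer(r, cs) / sum(r))), 0.03)
})

test_that("sampler matches the exhaustive Fisher null and r2dtable on 2x2", {
  r <- c(3, 2)
  cs <- c(2, 3)
  set.seed(5)
  a11 <- replicate(50000, patefield_sample(r, cs)[1, 1])
  emp <- tabulate(a11 + 1L, nbins = 3) / 50000
  theo <- dhyper(0:2, cs[1], cs[2], r[1])   # exact multiple hypergeometric
  expect_lt(sum(abs(emp - theo)) / 2, 0.02)   # total variation
  set.seed(6)
  ref <- vapply(r2dtable(20000, r, cs), function(t) t[1, 1], numeric(1))
  emp2 <- tabulate(ref + 1L, nbins = 3) / 20000
  expect_lt(sum(abs(emp - emp2)) / 2, 0.02)
})

test_that("null_test degenerates to a point mass when the table is forced", {
  net <- as_bipartite_network(matrix(c(1, 1), 1, 2))  # unique given marginals
  ens <- null_test(net, connectance, n_random = 100, seed = 1,
                   metric_name = "connectance")
  expect_true(all(ens$samples == ens$observed))
  expect_false(ens$significant)
  # total F is conserved by construction for any network
  net2 <- as_bipartite_network(random_valid_matrix(3, 4))
  ens2 <- null_test(net2, sum, n_random = 50, seed = 2, metric_name = "F")
  expect_true(all(ens2$samples == sum(net2$weights)))
})

test_that("null_test is deterministic given the seed and validates input", {
  net <- as_bipartite_network(random_valid_matrix(3, 3))
  a <- null_test(net, function(m) nodf(m), n_random = 50, seed = 42)
  b <- null_test(net, function(m) nodf(m), n_random = 50, seed = 42)
  expect_identical(a[c("samples", "ci_low", "ci_high", "significant")],
                   b[c("samples", "ci_low", "ci_high", "significant")])
  expect_error(null_test(net, sum, n_random = 1, seed = 1), "at least 2")
  expect_error(null_test(net, sum, n_random = 10), "seed")
  expect_lte(a$ci_low, a$ci_high)
  expect_length(a$samples, 50)
})

test_that("a strongly specialized table is detected against the null", {
  m <- diag(4) * 10 + 1   # heavy diagonal, light off-diagonal
  ens <- null_test(m, function(x) h2prime(x)$h2prime, n_random = 1000,
                   seed = 9, metric_name = "h2prime")
  expect_gt(ens$observed, ens$ci_high)
  expect_true(ens$significant)
})
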
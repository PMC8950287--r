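two_block <- labelled(kronecker(diag(2), matrix(1, 2, 2)))
three_block <- labelled(kronecker(diag(3), matrix(1, 2, 2)))

test_that("modularity_Q matches closed forms on planted block matrices", {
  labs <- c(rownames(two_block), colnames(two_block))
  one <- stats::setNames(rep(1L, 8), labs)
  expect_equal(modularity_Q(two_block, one), 0)
  planted <- stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2), labs)
  expect_equal(modularity_Q(two_block, planted), 0.5)   # 1 - 1/k, k = 2
  wrong <- stats::setNames(c(1, 2, 1, 2, 1, 2, 1, 2), labs)
  expect_lt(modularity_Q(two_block, wrong), 0.5)
  expect_error(modularity_Q(two_block, c(planted, bogus = 1)), "unknown")
  expect_error(modularity_Q(two_block, planted[-1]), "missing")
})

test_that("modularity_Q is invariant to relabeling and permutation", {
  set.seed(31)
  m <- labelled(random_valid_matrix(4, 5))
  labs <- c(rownames(m), colnames(m))
  g <- stats::setNames(sample(1:3, 9, replace = TRUE), labs)
  g2 <- stats::setNames(c(7, 2, 9)[g], labs)   # relabel modules
  expect_equal(modularity_Q(m, g), modularity_Q(m, g2))
  perm <- m[sample(4), sample(5)]
  expect_equal(modularity_Q(perm, g), modularity_Q(m, g))
})

test_that("find_modules recovers planted partitions with exact Q", {
  p2 <- find_modules(two_block, n_repetitions = 5, steps = 2000, seed = 7)
  expect_equal(p2$Q, 0.5)
  expect_equal(p2$n_modules, 2)
  p3 <- find_modules(three_block, n_repetitions = 10, steps = 3000, seed = 7)
  expect_equal(p3$Q, 2 / 3)
  expect_equal(p3$n_modules, 3)
  # self-consistency: returned Q equals Q of the returned assignment
  expect_equal(modularity_Q(three_block, p3$assignment), p3$Q)
  expect_equal(p3$Q, max(p3$repetition_scores))
})

test_that("best-of-restarts equals exhaustive maximization on tiny instances", {
  set.seed(17)
  for (i in 1:5) {
    m <- labelled(random_valid_matrix(3, 3, lambda = 1.5))
    found <- find_modules(m, n_repetitions = 20, steps = 1500, seed = i)$Q
    expect_equal(found, oracle_max_q(m), tolerance = 1e-10)
  }
})

test_that("find_modules is deterministic given the seed and checks input", {
  a <- find_modules(two_block, n_repetitions = 3, steps = 500, seed = 4)
  b <- find_modules(two_block, n_repetitions = 3, steps = 500, seed = 4)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$Q, b$Q)
  expect_error(find_modules(two_block, cooling = 1.5, seed = 1), "cooling")
  expect_error(find_modules(two_block, n_repetitions = 0, seed = 1),
               "positive")
  expect_error(find_modules(two_block, n_repetitions = 2, steps = 100),
               "seed")
})

test_that("planted modules in generated networks are recovered (ARI)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:20, function(s) {
    m <- generate_modular(9, 9, k = 3, within_share = 0.95, F_total = 300,
                          seed = s)
    part <- find_modules(labelled(m), n_repetitions = 8, steps = 3000,
                         seed = 100 + s)
    planted <- c(attr(m, "planted_rows"), attr(m, "planted_cols"))
    mclust::adjustedRandIndex(unname(part$assignment), planted)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.9)   # strong signal: near-perfect recovery
})
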
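test_that("generate_nested spans the nestedness gradient", {
  # staircase-feasible fill: the small-p limit is a perfect subset chain
  expect_gte(nodf(generate_nested(6, 6, p = 0.05, L = 21, seed = 1)), 0.9)
  # full matrix: all fills equal
  expect_equal(nodf(generate_nested(3, 4, p = 1, L = 12, seed = 1)), 0)
  expect_error(generate_nested(3, 3, p = 1, L = 2, seed = 1), "infeasible")
  # nested fill beats uniform-random fill at the same L
  set.seed(99)
  rand_nodf <- vapply(1:20, function(s) {
    m <- matrix(0L, 8, 8)
    m[sample(64, 24)] <- 1L
    nodf(pollinet:::repair_coverage(m, 24))
  }, numeric(1))
  nest_nodf <- vapply(1:20, function(s)
    nodf(generate_nested(8, 8, p = 0.3, L = 24, seed = s)), numeric(1))
  expect_gt(mean(nest_nodf), mean(rand_nodf))
})

test_that("generate_nested nodf is non-increasing in p on average", {
  means <- vapply(c(0.1, 0.5, 1, 2, 4), function(p) {
    mean(vapply(1:50, function(s)
      nodf(generate_nested(7, 9, p, 30, seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("generators are seed-deterministic and emit valid networks", {
  for (s in 1:5) {
    a <- generate_nested(5, 7, 0.8, 14, seed = s)
    expect_identical(a, generate_nested(5, 7, 0.8, 14, seed = s))
    expect_true(all(rowSums(a) > 0) && all(colSums(a) > 0))
    expect_equal(sum(a), 14)
    m <- generate_modular(6, 6, k = 2, within_share = 0.9, F_total = 120,
                          seed = s)
    expect_identical(m, generate_modular(6, 6, k = 2, within_share = 0.9,
                                         F_total = 120, seed = s))
    expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))
  }
})

test_that("generate_modular plants recoverable structure", {
  # all mass within modules: planted Q has the closed form 1 - sum(share^2)
  m <- generate_modular(6, 6, k = 2, within_share = 1, F_total = 200,
                        seed = 3)
  planted <- stats::setNames(c(attr(m, "planted_rows"),
                               attr(m, "planted_cols")),
                             c(paste0("p", 1:6), paste0("a", 1:6)))
  blocks <- vapply(unique(attr(m, "planted_rows")), function(b)
    sum(m[attr(m, "planted_rows") == b, attr(m, "planted_cols") == b]),
    numeric(1))
  expect_equal(modularity_Q(labelled(m), planted),
               1 - sum((blocks / sum(m))^2))
  # strong vs no signal
  strong <- find_modules(labelled(m), n_repetitions = 5, steps = 2000,
                         seed = 11)
  expect_gt(strong$Q, 0.4)
  weak <- generate_modular(6, 6, k = 2, within_share = 0.55, F_total = 200,
                           seed = 3)
  expect_lt(modularity_Q(labelled(weak),
                         stats::setNames(c(attr(weak, "planted_rows"),
                                           attr(weak, "planted_cols")),
                                         c(paste0("p", 1:6),
                                           paste0("a", 1:6)))), 0.15)
  expect_error(generate_modular(4, 4, k = 5, within_share = 0.9, 100, 1),
               "k must not")
  expect_error(generate_modular(4, 4, k = 2, within_share = 0.4, 100, 1),
               "within_share")
})

test_that("degree-sequence realization is exact or returns a verdict", {
  expect_equal(unname(realize_degree_sequence(c(2), c(1, 1))$matrix),
               matrix(1L, 1, 2))
  expect_false(realize_degree_sequence(c(3), c(1))$feasible)
  expect_false(realize_degree_sequence(c(2, 2), c(4),
                                       seed = 1)$feasible)  # degree > partners
  set.seed(41)
  for (i in 1:20) {
    b <- (random_valid_matrix(sample(3:6, 1), sample(3:6, 1)) > 0) + 0L
    rl <- realize_degree_sequence(rowSums(b), colSums(b), seed = i)
    expect_true(rl$feasible)
    expect_equal(sort(unname(rowSums(rl$matrix))), sort(unname(rowSums(b))))
    expect_equal(sort(unname(colSums(rl$matrix))), sort(unname(colSums(b))))
    expect_true(all(rl$matrix %in% 0:1))
  }
})

test_that("the survey fixture encodes the published tables", {
  fx <- load_fixture()
  expect_length(fx$plant_species, 12)
  expect_length(fx$pollinator_species, 19)
  expect_equal(sum(fx$plant_degrees), 42)
  expect_equal(sum(fx$pollinator_degrees), 42)
  expect_equal(unname(fx$plant_degrees["Viola mandshurica"]), 0L)
  d149 <- fx$daily_params[fx$daily_params$day == 149, ]
  expect_equal(unlist(d149[c("R", "A", "L", "links_added", "raw_nodf",
                             "max_nodf")], use.names = FALSE),
               c(10, 9, 17, 3, 0.216, 0.469))
  expect_equal(dim(fx$hourly_visits), c(3, 7))
  # realization of the printed degree sequences
  net <- fixture_network(fx)
  expect_equal(n_links(net), 42)
  expect_equal(round(connectance(net), 3), 0.201)
})
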
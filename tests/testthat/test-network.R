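test_that("build_network aggregates records and registers isolated species", {
  rec <- data.frame(day = c(147, 147, 149, 146),
                    plant = c("p1", "p1", "p2", "p3"),
                    pollinator = c("a1", "a1", "a2", "a1"),
                    visits = c(2, 1, 4, 0))
  net <- build_network(rec)
  expect_equal(unname(net$weights["p1", "a1"]), 3)
  expect_equal(unname(net$weights["p2", "a2"]), 4)
  expect_equal(net$isolated, "p3")      # zero total visits -> register only
  expect_equal(dim(net$weights), c(2, 2))
  # single record
  one <- build_network(data.frame(day = 1, plant = "p1", pollinator = "a1",
                                  visits = 3))
  expect_equal(unname(one$weights), matrix(3L, 1, 1))
  # day filtering
  d149 <- build_network(rec, day_filter = 149)
  expect_equal(rownames(d149$weights), "p2")
  expect_error(build_network(rec, day_filter = 999), "empty network")
  expect_error(build_network(transform(rec, visits = c(-1, 1, 1, 1))),
               "non-negative")
  expect_error(build_network(transform(rec, day = c(0, 1, 1, 1))), "Julian")
})

test_that("label order does not affect structure; sort flag is honoured", {
  rec <- data.frame(day = 1, plant = c("z", "a", "z"),
                    pollinator = c("y", "b", "b"), visits = c(1, 2, 3))
  net <- build_network(rec)
  expect_equal(rownames(net$weights), c("z", "a"))       # first appearance
  nets <- build_network(rec, sort_labels = TRUE)
  expect_equal(rownames(nets$weights), c("a", "z"))
  expect_equal(sum(net$weights), sum(nets$weights))
  expect_equal(nodf(to_binary(net)$weights), nodf(to_binary(nets)$weights))
})

test_that("marginal totals are consistent on random networks", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_valid_matrix(sample(2:6, 1), sample(2:6, 1))
    net <- as_bipartite_network(m)
    expect_equal(sum(rowSums(net$weights)), sum(colSums(net$weights)))
    expect_equal(sum(net$weights > 0), n_links(net))
  }
})

test_that("interaction CSV round-trips bit-exactly and reports parse errors", {
  rec <- data.frame(day = c(146L, 149L), plant = c("Arabis gemmifera", "p2"),
                    pollinator = c("a1", "a2"), visits = c(5L, 1L),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interactions_csv(rec, path)
  expect_identical(read_interactions_csv(path), rec)
  # header-only file -> empty collection
  writeLines("day,plant,pollinator,visits", path)
  expect_equal(nrow(read_interactions_csv(path)), 0)
  # negative visits named by row
  writeLines(c("day,plant,pollinator,visits", "1,p,a,2", "1,p,b,-1"), path)
  expect_error(read_interactions_csv(path), "row 2")
  writeLines(c("day,plant,pollinator", "1,p,a"), path)
  expect_error(read_interactions_csv(path), "visits")
})

test_that("matrix TSV round-trips", {
  m <- labelled(matrix(c(3L, 0L, 1L, 2L), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(read_matrix_tsv(path)$weights, m)
})

test_that("to_binary maps positive cells to 1 and keeps L", {
  m <- matrix(c(3, 0, 1, 2), 2, 2)
  b <- to_binary(m)
  expect_equal(unname(b$weights), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_equal(n_links(b), n_links(m))
  allone <- matrix(1L, 3, 4)
  expect_equal(unname(to_binary(allone)$weights), allone)
})

test_that("the shipped synthetic realization reproduces the survey totals", {
  net <- build_network(read_interactions_csv(fixture_interactions_csv()))
  expect_equal(dim(net$weights), c(11, 19))
  expect_equal(n_links(net), 42)
  expect_equal(net$isolated, "Viola mandshurica")
  expect_equal(n_links(to_binary(net)), 42)
})
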
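test_that("path and star geometries give hand-computed centralities", {
  # plant a -- pollinator x -- plant b
  path <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  tab <- centralities(path)
  expect_equal(tab$bc[tab$species == "x"], 1)
  expect_equal(tab$cc[tab$species == "x"], 1 / 2)
  expect_equal(tab$cc[tab$species %in% c("a", "b")], c(1 / 3, 1 / 3))
  # star: one pollinator linked to 4 plants
  star <- matrix(1, 4, 1, dimnames = list(paste0("p", 1:4), "hub"))
  tabs <- centralities(star)
  expect_equal(tabs$bc[tabs$species == "hub"], 1)
  expect_equal(tabs$bc[tabs$level == "plant"], rep(0, 4))
})

test_that("centralities equal the all-pairs-BFS oracle on random graphs", {
  set.seed(23)
  n_done <- 0
  while (n_done < 100) {
    nr <- sample(3:8, 1)
    nc <- sample(3:8, 1)
    b <- matrix(rbinom(nr * nc, 1, 0.4), nr, nc)
    if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
    n <- nr + nc
    adj <- rbind(cbind(matrix(FALSE, nr, nr), b > 0),
                 cbind(t(b > 0), matrix(FALSE, nc, nc)))
    # oracle handles disconnected graphs too; compare as-is
    ref <- oracle_centrality(adj)
    tab <- centralities(labelled(b))
    expect_equal(tab$bc, ref$bc, tolerance = 1e-10)
    expect_equal(tab$cc, ref$cc, tolerance = 1e-10)
    n_done <- n_done + 1
  }
})

test_that("unnormalized betweenness on a path equals total path throughput", {
  # bipartite path p1-a1-p2-a2-p3: through-traffic sum = sum over pairs of
  # (d(s,t) - 1) intermediate vertices
  b <- rbind(c(1, 0), c(1, 1), c(0, 1))
  adj <- rbind(cbind(matrix(FALSE, 3, 3), b > 0),
               cbind(t(b > 0), matrix(FALSE, 2, 2)))
  ref <- oracle_centrality(adj)
  d <- oracle_bfs_dist(adj)
  expect_equal(sum(ref$bc_raw), sum((d[upper.tri(d)] - 1)))
})

test_that("centralities are invariant under species relabeling", {
  set.seed(29)
  b <- (random_valid_matrix(4, 5) > 0) + 0
  t1 <- centralities(labelled(b))
  b2 <- b
  dimnames(b2) <- list(paste0("plant_", LETTERS[1:4]), paste0("ins_", 1:5))
  t2 <- centralities(b2)
  expect_equal(t1$bc, t2$bc)
  expect_equal(t1$cc, t2$cc)
})

test_that("projection mode computes per-level centralities", {
  b <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1))
  tab <- centralities(labelled(b), graph_mode = "projection")
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$bc >= 0 & tab$bc <= 1))
})

test_that("keystone ranking identifies the published keystone species", {
  tab <- fixture_centrality_table()
  top_poll <- keystone_rank(tab, "pollinator")
  expect_equal(top_poll$species[1], "Lasioglossum virideglaucum")
  expect_true(top_poll$keystone[1])
  expect_equal(top_poll$degree[1], 8L)
  plants <- keystone_rank(tab, "plant")
  expect_equal(plants$species[plants$bc == max(plants$bc, na.rm = TRUE) &
                                !is.na(plants$bc)], "Arabis gemmifera")
  # the degree-0 plant sorts last with undefined centralities
  expect_equal(plants$species[nrow(plants)], "Viola mandshurica")
  # idempotence / order stability
  expect_equal(keystone_rank(tab, "plant")$species, plants$species)
})

test_that("a species dominating all three scores ranks first", {
  tab <- data.frame(species = c("s1", "s2", "s3"), level = "pollinator",
                    degree = c(5L, 2L, 1L), bc = c(0.8, 0.1, 0),
                    cc = c(0.3, 0.2, 0.1))
  expect_equal(keystone_rank(tab, "pollinator")$species[1], "s1")
  expect_error(keystone_rank(tab, "plant"), "no species")
})
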
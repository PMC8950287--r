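#' Degree, betweenness and closeness centrality of every species
#'
#' Centralities are computed on the binary structure of the network.
#' In the default `"bipartite"` mode one undirected graph over all
#' connected species (plants + pollinators) is used. In `"projection"`
#' mode each trophic level is projected onto a one-mode graph (two
#' species adjacent when they share at least one partner) and
#' centralities are computed per level.
#'
#' Conventions: betweenness is shortest-path betweenness normalized by
#' `(n-1)(n-2)/2` (n = vertices of the graph at hand), so BC lies in
#' \[0, 1\]. Closeness is the reciprocal of the sum of geodesic
#' distances to all *reachable* vertices, `CC = 1 / sum(d)`, without the
#' usual (n-1) rescaling; unreachable pairs contribute nothing and the
#' fraction of reachable pairs is reported alongside. Isolated species
#' get degree 0 and `NA` centralities.
#'
#' @param net a `bipartite_network` or matrix.
#' @param graph_mode `"bipartite"` (default) or `"projection"`.
#' @return object of class `centrality_table`: a data.frame with
#'   columns `species`, `level`, `degree`, `bc`, `cc`, plus attribute
#'   `reachable_fraction`.
#' @export
centralities <- function(net, graph_mode = c("bipartite", "projection")) {
  graph_mode <- match.arg(graph_mode)
  net <- as_bipartite_network(net)
  b <- net$weights > 0
  lev <- c(rep("plant", nrow(b)), rep("pollinator", ncol(b)))
  labs <- c(rownames(b), colnames(b))
  deg <- c(rowSums(b), colSums(b))
  if (graph_mode == "bipartite") {
    g <- igraph::graph_from_biadjacency_matrix(b)
    sc <- graph_centrality(g)
    bc <- sc$bc
    cc <- sc$cc
    reach <- sc$reach
  } else {
    bc <- cc <- numeric(length(labs))
    reach <- numeric(0)
    proj <- list(plant = (b %*% t(b)) > 0, pollinator = (t(b) %*% b) > 0)
    for (side in names(proj)) {
      adj <- proj[[side]]
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      sc <- graph_centrality(g)
      bc[lev == side] <- sc$bc
      cc[lev == side] <- sc$cc
      reach <- c(reach, sc$reach)
    }
    reach <- mean(reach)
  }
  out <- data.frame(species = labs, level = lev,
                    degree = as.integer(deg), bc = bc, cc = cc,
                    stringsAsFactors = FALSE)
  n_iso <- length(net$isolated_plants) + length(net$isolated_pollinators)
  if (n_iso) {
    iso <- data.frame(
      species = c(net$isolated_plants, net$isolated_pollinators),
      level = c(rep("plant", length(net$isolated_plants)),
                rep("pollinator", length(net$isolated_pollinators))),
      degree = rep(0L, n_iso), bc = rep(NA_real_, n_iso),
      cc = rep(NA_real_, n_iso),
      stringsAsFactors = FALSE)
    out <- rbind(out, iso)
  }
  rownames(out) <- NULL
  structure(out, class = c("centrality_table", "data.frame"),
            reachable_fraction = if (length(reach)) reach else NA_real_,
            graph_mode = graph_mode)
}

graph_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  bc <- if (n > 2L) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    rep(0, n)
  }
  d <- igraph::distances(g)
  diag(d) <- Inf
  cc <- apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (!length(fin)) NA_real_ else 1 / sum(fin)
  })
  reach <- if (n > 1L) sum(is.finite(d)) / (n * (n - 1)) else 1
  list(bc = unname(bc), cc = unname(cc), reach = reach)
}

#' Rank species by composite centrality and flag the keystone
#'
#' Species of one trophic level are ranked by the mean of their ranks
#' (descending) on unweighted degree, betweenness and closeness; ties
#' are broken by degree, then label. Species with undefined centralities
#' (isolated) sort last. The top species is the keystone candidate.
#'
#' @param table a `centrality_table` (or data.frame with `species`,
#'   `level`, `degree`, `bc`, `cc`).
#' @param level `"plant"` or `"pollinator"`.
#' @return data.frame ordered best-first, with columns of `table` plus
#'   `mean_rank` and logical `keystone` (TRUE on the first row).
#' @export
keystone_rank <- function(table, level = c("pollinator", "plant")) {
  level <- match.arg(level)
  tab <- table[table$level == level, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no species at level ", dQuote(level))
  rk <- function(x) rank(-x, ties.method = "average", na.last = "keep")
  mean_rank <- rowMeans(cbind(rk(tab$degree), rk(tab$bc), rk(tab$cc)),
                        na.rm = FALSE)
  mean_rank[is.na(mean_rank)] <- Inf  # isolated species sort last
  ord <- order(mean_rank, -tab$degree, tab$species)
  tab <- tab[ord, , drop = FALSE]
  tab$mean_rank <- mean_rank[ord]
  tab$keystone <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}
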
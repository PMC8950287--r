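# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately written in a different style
# (explicit partner sets, BFS path enumeration) from the code they test.

# NODF by explicit partner-set enumeration
oracle_nodf <- function(m) {
  m <- (as.matrix(m) > 0)
  line_score <- function(sets) {
    n <- length(sets)
    if (n < 2) return(c(0, 0))
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- sets[[i]]; b <- sets[[j]]
        if (length(a) == length(b)) next
        small <- if (length(a) < length(b)) a else b
        big <- if (length(a) < length(b)) b else a
        tot <- tot + length(intersect(small, big)) / length(small)
      }
    }
    c(tot, n * (n - 1) / 2)
  }
  rows <- lapply(seq_len(nrow(m)), function(i) which(m[i, ]))
  cols <- lapply(seq_len(ncol(m)), function(j) which(m[, j]))
  r <- line_score(rows)
  cs <- line_score(cols)
  (r[1] + cs[1]) / (r[2] + cs[2])
}

# all-pairs BFS distances on an adjacency matrix
oracle_bfs_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# betweenness/closeness by explicit enumeration of all shortest paths
# (recursive walk over the BFS distance structure); bc normalized by
# (n-1)(n-2)/2, cc = 1/sum(finite distances)
oracle_centrality <- function(adj) {
  n <- nrow(adj)
  d <- oracle_bfs_dist(adj)
  count_paths <- function(s, t) {
    # returns c(total paths, paths through each vertex)
    through <- numeric(n)
    walk <- function(v, visited) {
      if (v == t) {
        for (u in setdiff(visited, c(s, t))) {
          through[u] <<- through[u] + 1
        }
        return(1)
      }
      tot <- 0
      for (u in which(adj[v, ])) {
        if (d[s, u] == d[s, v] + 1 && d[u, t] == d[v, t] - 1) {
          tot <- tot + walk(u, c(visited, u))
        }
      }
      tot
    }
    c(walk(s, integer(0)), through)
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      res <- count_paths(s, t)
      if (res[1] > 0) bc <- bc + res[-1] / res[1]
    }
  }
  cc <- sapply(seq_len(n), function(v) {
    fin <- d[v, -v][is.finite(d[v, -v])]
    if (!length(fin)) NA_real_ else 1 / sum(fin)
  })
  list(bc = bc / ((n - 1) * (n - 2) / 2), cc = cc, bc_raw = bc)
}

# all set partitions of n elements as restricted-growth strings
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (g in seq_len(maxid + 1)) {
      rec(c(prefix, g), max(maxid, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum of quantitative bipartite modularity
oracle_max_q <- function(m) {
  labs <- c(rownames(m), colnames(m))
  best <- -Inf
  for (p in oracle_partitions(length(labs))) {
    q <- modularity_Q(m, stats::setNames(p, labs))
    if (q > best) best <- q
  }
  best
}

# random quantitative matrix with no empty row/column
random_valid_matrix <- function(nr, nc, lambda = 1.2) {
  repeat {
    m <- matrix(stats::rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

labelled <- function(m) {
  dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                      paste0("a", seq_len(ncol(m))))
  m
}
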
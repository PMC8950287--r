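#' Quantitative bipartite modularity Q of a given partition
#'
#' Barber-type modularity of a quantitative interaction matrix A under a
#' joint module assignment of plants and pollinators:
#' `Q = (1/F) * sum_ij (A_ij - k_i d_j / F) * delta(g_i, g_j)`,
#' with F the matrix total, `k_i` row totals, `d_j` column totals and
#' delta equal to 1 when plant i and pollinator j share a module. This
#' is the objective that QuanBiMo-style optimizers maximize; higher Q
#' means more interaction weight concentrated within modules than the
#' degree-based expectation.
#'
#' @param net a `bipartite_network` or quantitative matrix.
#' @param assignment named integer (or factor/character) vector mapping
#'   every plant and pollinator label to a module id; plants and
#'   pollinators share one id space.
#' @return Q value (at most 1; 0 for the all-in-one-module partition).
#' @export
modularity_Q <- function(net, assignment) {
  m <- if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                        paste0("a", seq_len(ncol(m))))
  }
  labs <- c(rownames(m), colnames(m))
  if (!all(labs %in% names(assignment))) {
    stop("assignment is missing species: ",
         paste(setdiff(labs, names(assignment)), collapse = ", "))
  }
  if (!all(names(assignment) %in% labs)) {
    stop("assignment has unknown species label(s): ",
         paste(setdiff(names(assignment), labs), collapse = ", "))
  }
  g <- as.integer(factor(assignment))
  names(g) <- names(assignment)
  f <- sum(m)
  b <- m - outer(rowSums(m), colSums(m)) / f
  same <- outer(g[rownames(m)], g[colnames(m)], "==")
  sum(b[same]) / f
}

# Q from integer module vectors for rows and columns (internal fast path)
q_from_groups <- function(b, f, grow, gcol) {
  sum(b[outer(grow, gcol, "==")]) / f
}

#' Find modules by simulated annealing
#'
#' Stochastic maximization of [modularity_Q()]. Each repetition runs an
#' independent simulated-annealing chain: moves are single-species
#' reassignments (to an existing or a fresh module), occasional merges
#' of two modules and random splits of one module; improving moves are
#' always accepted, worsening moves with probability `exp(dQ / T)`, and
#' the temperature cools geometrically (`T <- alpha * T`) after each
#' move. The best partition over all repetitions is returned (the
#' repetition count defaults to 100, the convention for QuanBiMo-style
#' analyses, with the best-scoring run selected).
#'
#' @param net a `bipartite_network` or quantitative matrix.
#' @param n_repetitions independent annealing restarts (default 100).
#' @param steps moves per repetition (default 1e4).
#' @param t0 initial temperature (default 0.02, on the Q scale).
#' @param cooling geometric cooling factor in (0, 1) (default 0.995;
#'   applied every `ceiling(steps/1000)` moves so the schedule reaches
#'   ~t0 * 0.995^1000 regardless of `steps`).
#' @param seed integer RNG seed (required).
#' @return object of class `module_partition`: named `assignment`
#'   (module ids 1..k over all species), `Q`, `n_modules`,
#'   `repetition_scores`, `seed`.
#' @export
find_modules <- function(net, n_repetitions = 100, steps = 1e4,
                         t0 = 0.02, cooling = 0.995, seed) {
  if (missing(seed)) stop("seed is required")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)")
  if (steps < 1 || n_repetitions < 1) {
    stop("steps and n_repetitions must be positive")
  }
  m <- if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                        paste0("a", seq_len(ncol(m))))
  }
  nr <- nrow(m)
  nc <- ncol(m)
  f <- sum(m)
  b <- (m - outer(rowSums(m), colSums(m)) / f) / f  # Q = sum over same-module
  set.seed(as.integer(seed))
  best_q <- -Inf
  best_g <- NULL
  rep_scores <- numeric(n_repetitions)
  n_sp <- nr + nc
  cool_every <- max(1L, ceiling(steps / 1000))
  for (rep_i in seq_len(n_repetitions)) {
    g <- sample.int(max(2L, min(n_sp, nr)), n_sp, replace = TRUE)
    q <- anneal_q(b, g, nr, nc, steps, t0, cooling, cool_every)
    g <- q$g
    qv <- q$q
    rep_scores[rep_i] <- qv
    if (qv > best_q + 1e-12) {
      best_q <- qv
      best_g <- g
    }
  }
  # canonical module ids: 1..k in order of first appearance
  ids <- match(best_g, unique(best_g))
  assignment <- stats::setNames(ids, c(rownames(m), colnames(m)))
  structure(
    list(assignment = assignment, Q = best_q,
         n_modules = length(unique(ids)),
         repetition_scores = rep_scores, seed = seed),
    class = "module_partition")
}

# One annealing chain over joint module vector g (rows then cols).
# b is the (A - kd/F)/F matrix, so Q is the sum of b over same-module
# (row, col) pairs; single-species moves use O(n) delta updates.
anneal_q <- function(b, g, nr, nc, steps, t0, cooling, cool_every) {
  grow <- g[seq_len(nr)]
  gcol <- g[nr + seq_len(nc)]
  q <- q_from_groups(b, 1, grow, gcol)
  temp <- t0
  n_sp <- nr + nc
  for (s in seq_len(steps)) {
    kind <- sample.int(20L, 1L)  # 18/20 reassign, 1/20 merge, 1/20 split
    if (kind <= 18L) {
      v <- sample.int(n_sp, 1L)
      mods <- unique(c(grow, gcol))
      newmod <- sample(c(mods, max(mods) + 1L), 1L)
      if (v <= nr) {
        old <- grow[v]
        if (newmod == old) next
        dq <- sum(b[v, gcol == newmod]) - sum(b[v, gcol == old])
        if (dq > 0 || stats::runif(1) < exp(dq / temp)) {
          grow[v] <- newmod
          q <- q + dq
        }
      } else {
        j <- v - nr
        old <- gcol[j]
        if (newmod == old) next
        dq <- sum(b[grow == newmod, j]) - sum(b[grow == old, j])
        if (dq > 0 || stats::runif(1) < exp(dq / temp)) {
          gcol[j] <- newmod
          q <- q + dq
        }
      }
    } else {
      mods <- unique(c(grow, gcol))
      if (kind == 19L && length(mods) >= 2L) {       # merge two modules
        pick <- sample(mods, 2L)
        ng_row <- ifelse(grow == pick[2], pick[1], grow)
        ng_col <- ifelse(gcol == pick[2], pick[1], gcol)
      } else {                                        # split one module
        tgt <- sample(mods, 1L)
        members <- c(which(grow == tgt), nr + which(gcol == tgt))
        if (length(members) < 2L) next
        half <- sample(members, ceiling(length(members) / 2))
        fresh <- max(mods) + 1L
        ng_row <- grow
        ng_col <- gcol
        ng_row[half[half <= nr]] <- fresh
        ng_col[half[half > nr] - nr] <- fresh
      }
      nq <- q_from_groups(b, 1, ng_row, ng_col)
      dq <- nq - q
      if (dq > 0 || stats::runif(1) < exp(dq / temp)) {
        grow <- ng_row
        gcol <- ng_col
        q <- nq
      }
    }
    if (s %% cool_every == 0L) temp <- temp * cooling
  }
  # final greedy polish: steepest single-species moves to local optimum
  repeat {
    improved <- FALSE
    mods <- unique(c(grow, gcol))
    for (v in seq_len(n_sp)) {
      if (v <= nr) {
        cur <- grow[v]
        gains <- vapply(mods, function(mm) sum(b[v, gcol == mm]), numeric(1))
      } else {
        cur <- gcol[v - nr]
        gains <- vapply(mods, function(mm) sum(b[grow == mm, v - nr]),
                        numeric(1))
      }
      bestm <- mods[which.max(gains)]
      dq <- max(gains) - gains[match(cur, mods)]
      if (dq > 1e-12 && bestm != cur) {
        if (v <= nr) grow[v] <- bestm else gcol[v - nr] <- bestm
        q <- q + dq
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(g = c(grow, gcol), q = q_from_groups(b, 1, grow, gcol))
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f (best of %d runs, seed %d)\n",
              x$n_modules, x$Q, length(x$repetition_scores), x$seed))
  invisible(x)
}

#' Module roster grouped by trophic level
#'
#' @param partition a `module_partition`.
#' @param net the network it was fitted to.
#' @return data.frame with columns `module`, `level`, `species`.
#' @export
module_roster <- function(partition, net) {
  net <- as_bipartite_network(net)
  a <- partition$assignment
  lev <- ifelse(names(a) %in% net$plants, "plant", "pollinator")
  out <- data.frame(module = unname(a), level = lev, species = names(a),
                    stringsAsFactors = FALSE)
  out[order(out$module, out$level, out$species), , drop = FALSE]
}
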
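#' Generate a nested binary interaction matrix
#'
#' Fills cells below the curve `(i/R)^p + (j/A)^p <= 1` (rows and
#' columns in decreasing-generalist order), then thins or augments to
#' exactly `L` links while keeping every line non-empty. Smaller `p`
#' bends the fill boundary outward, producing a more nested matrix;
#' large `p` approaches an anti-nested diagonal band.
#'
#' @param R,A dimensions.
#' @param p fill-boundary exponent (> 0); smaller = more nested.
#' @param L target link count, `max(R, A) <= L <= R * A`.
#' @param seed RNG seed (used for tie-breaking jitter and thinning).
#' @return binary R x A matrix with exactly `L` ones, no empty lines.
#' @export
generate_nested <- function(R, A, p, L, seed) {
  if (L < max(R, A) || L > R * A) stop("infeasible link count")
  if (p <= 0) stop("p must be positive")
  set.seed(as.integer(seed))
  idx <- expand.grid(i = seq_len(R), j = seq_len(A))
  # fill-boundary score: low near the generalist corner (1,1); tiny
  # seeded jitter breaks ties reproducibly
  score <- (idx$i / (R + 1))^p + (idx$j / (A + 1))^p +
    stats::runif(nrow(idx), 0, 1e-9)
  m <- matrix(0L, R, A)
  m[score <= 1] <- 1L
  need <- L - sum(m)
  if (need < 0) {
    # thin: drop boundary cells (highest score) first
    filled <- which(m == 1L)
    drop <- filled[order(score[filled], decreasing = TRUE)][seq_len(-need)]
    m[drop] <- 0L
  } else if (need > 0) {
    # augment in maximally nested order: first row and first column,
    # then remaining cells packed toward the generalist corner
    target <- greedy_nested_fill(R, A, min(R * A, L))
    add <- which(target == 1L & m == 0L)
    add <- add[order(score[add])]
    if (length(add) < need) {
      extra <- which(m == 0L & target == 0L)
      add <- c(add, extra[order(score[extra])])
    }
    m[add[seq_len(need)]] <- 1L
  }
  repair_coverage(m, L)
}

# move ones around so that every row/column has one, preserving count
repair_coverage <- function(m, L) {
  stopifnot(sum(m) == L)
  repeat {
    er <- which(rowSums(m) == 0)
    ec <- which(colSums(m) == 0)
    if (!length(er) && !length(ec)) return(m)
    if (length(er)) {
      i <- er[1]
      # take a 1 from the most-filled row, in its most-filled column
      donor <- which.max(rowSums(m) * (rowSums(m) > 1))
      j <- which(m[donor, ] == 1L)[which.max(colSums(m)[m[donor, ] == 1L])]
      m[donor, j] <- 0L
      m[i, j] <- 1L
    } else {
      j <- ec[1]
      donor <- which.max(colSums(m) * (colSums(m) > 1))
      i <- which(m[, donor] == 1L)[which.max(rowSums(m)[m[, donor] == 1L])]
      m[i, donor] <- 0L
      m[i, j] <- 1L
    }
  }
}

#' Generate a quantitative matrix with planted modules
#'
#' Splits plants and pollinators as evenly as possible into `k` planted
#' modules and distributes `F` visits multinomially: a fraction
#' `within_share` of the probability mass is spread uniformly over
#' within-module cells, the rest over between-module cells. After
#' sampling, empty lines are repaired by moving single visits into the
#' empty line's within-module cells, so the result is a valid network.
#'
#' @param R,A dimensions; `k <= min(R, A)`.
#' @param k number of planted modules.
#' @param within_share within-module probability mass, in (0.5, 1].
#' @param F_total total number of visits.
#' @param seed RNG seed.
#' @return integer matrix with attributes `planted_rows`,
#'   `planted_cols` (module labels 1..k).
#' @export
generate_modular <- function(R, A, k, within_share, F_total, seed) {
  if (k > min(R, A)) stop("k must not exceed min(R, A)")
  if (within_share <= 0.5 || within_share > 1) {
    stop("within_share must be in (0.5, 1]")
  }
  set.seed(as.integer(seed))
  grow <- sort(rep_len(seq_len(k), R))
  gcol <- sort(rep_len(seq_len(k), A))
  within <- outer(grow, gcol, "==")
  prob <- matrix(0, R, A)
  prob[within] <- within_share / sum(within)
  if (within_share < 1) prob[!within] <- (1 - within_share) / sum(!within)
  m <- matrix(as.integer(stats::rmultinom(1, F_total, as.vector(prob))), R, A)
  # repair empty lines with single within-module visits
  for (i in which(rowSums(m) == 0)) {
    j <- which(gcol == grow[i])[1]
    m[i, j] <- 1L
  }
  for (j in which(colSums(m) == 0)) {
    i <- which(grow == gcol[j])[1]
    m[i, j] <- 1L
  }
  attr(m, "planted_rows") <- grow
  attr(m, "planted_cols") <- gcol
  m
}

#' Realize a bipartite degree sequence as a binary matrix
#'
#' Checks Gale-Ryser feasibility of the paired plant/pollinator degree
#' sequences and, when feasible, constructs one realization by
#' maximal-first placement: the plant with the largest remaining degree
#' is connected to the pollinators with the largest remaining degrees
#' (random tie-breaking among equal remaining degrees).
#'
#' @param plant_degrees,pollinator_degrees non-negative integer degree
#'   vectors (names become species labels). Zero-degree species are
#'   allowed and yield no matrix line.
#' @param seed RNG seed for tie-breaking.
#' @return list with `feasible`; when feasible also `matrix` (binary,
#'   labelled, zero-degree species omitted).
#' @export
realize_degree_sequence <- function(plant_degrees, pollinator_degrees, seed = 1) {
  pd <- as.integer(plant_degrees)
  ad <- as.integer(pollinator_degrees)
  if (is.null(names(plant_degrees))) {
    names(pd) <- paste0("plant_", seq_along(pd))
  } else names(pd) <- names(plant_degrees)
  if (is.null(names(pollinator_degrees))) {
    names(ad) <- paste0("pollinator_", seq_along(ad))
  } else names(ad) <- names(pollinator_degrees)
  pd <- pd[pd > 0]
  ad <- ad[ad > 0]
  if (sum(pd) != sum(ad)) {
    return(list(feasible = FALSE, reason = "degree sums differ"))
  }
  if (length(pd) == 0L) return(list(feasible = FALSE, reason = "no links"))
  if (any(pd > length(ad)) || any(ad > length(pd))) {
    return(list(feasible = FALSE, reason = "degree exceeds partner count"))
  }
  # Gale-Ryser: sorted descending p, sum_{i<=k} p_i <= sum_j min(a_j, k)
  ps <- sort(pd, decreasing = TRUE)
  for (k in seq_along(ps)) {
    if (sum(ps[seq_len(k)]) > sum(pmin(ad, k))) {
      return(list(feasible = FALSE, reason = "Gale-Ryser condition fails"))
    }
  }
  set.seed(as.integer(seed))
  m <- matrix(0L, length(pd), length(ad), dimnames = list(names(pd), names(ad)))
  rem_p <- pd
  rem_a <- ad
  while (any(rem_p > 0)) {
    i <- which.max(rem_p)
    # pollinators by remaining degree, random order within ties
    ord <- order(rem_a + stats::runif(length(rem_a), 0, 0.5),
                 decreasing = TRUE)
    ord <- ord[m[i, ord] == 0L & rem_a[ord] > 0]
    take <- ord[seq_len(rem_p[i])]
    m[i, take] <- 1L
    rem_a[take] <- rem_a[take] - 1L
    rem_p[i] <- 0L
  }
  list(feasible = TRUE, matrix = m)
}
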
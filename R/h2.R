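#' Complementary specialization H2'
#'
#' Network-level specialization of a quantitative interaction matrix,
#' based on the two-dimensional Shannon entropy of interaction
#' frequencies. With `p_ij = a_ij / F` (F the matrix total),
#' `H2 = -sum p_ij log p_ij` over positive cells. H2 is rescaled between
#' the maximum (most even) and minimum (most concentrated) entropy
#' attainable by any non-negative integer table sharing the observed row
#' and column totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, clamped to \[0, 1\].
#' 0 means complete generalization (interactions follow marginal
#' expectation), 1 complete specialization.
#'
#' The entropy extremes are found by exhaustive enumeration of all
#' integer tables with the observed marginals when the table is small
#' (at most 12 cells and the enumeration stays below a count cap),
#' otherwise by deterministic heuristics: the maximum from a
#' largest-remainder integerization of the independence expectations
#' `r_i c_j / F`, the minimum from a greedy concentration fill that
#' repeatedly pairs the largest remaining marginals. Natural logarithms
#' throughout.
#'
#' @param net a `bipartite_network` or non-negative integer matrix with
#'   total F >= 2.
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"` or
#'   `"heuristic"`.
#' @return list with `H2`, `H2max`, `H2min` (nats) and `h2prime`.
#' @export
h2prime <- function(net, method = c("auto", "exhaustive", "heuristic")) {
  method <- match.arg(method)
  m <- if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
  if (any(m < 0) || any(m != floor(m))) {
    stop("h2prime requires a non-negative integer matrix")
  }
  f <- sum(m)
  if (f == 0) stop("h2prime undefined for an empty (all-zero) matrix")
  h2 <- shannon_entropy(m)
  r <- rowSums(m)
  cs <- colSums(m)
  ex <- h2_extremes(r, cs, method = method)
  denom <- ex$H2max - ex$H2min
  if (denom <= .Machine$double.eps^0.5) {
    warning("degenerate marginals: H2max = H2min; h2prime set to 0")
    h2p <- 0
  } else {
    h2p <- min(1, max(0, (ex$H2max - h2) / denom))
  }
  list(H2 = h2, H2max = ex$H2max, H2min = ex$H2min, h2prime = h2p)
}

shannon_entropy <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

#' Entropy extremes over integer tables with fixed marginals
#'
#' @param r,cs row and column totals (non-negative integers, equal sums).
#' @param method see [h2prime()].
#' @param enum_cap maximum number of tables the exhaustive route may
#'   visit before `"auto"` falls back to the heuristics.
#' @return list with `H2max`, `H2min`, `method` actually used, and
#'   witness tables `table_max`, `table_min`.
#' @export
h2_extremes <- function(r, cs, method = c("auto", "exhaustive", "heuristic"),
                        enum_cap = 2e5) {
  method <- match.arg(method)
  if (sum(r) != sum(cs)) stop("marginal sums differ")
  use_exhaustive <- switch(method,
    exhaustive = TRUE,
    heuristic = FALSE,
    auto = length(r) * length(cs) <= 12L)
  if (use_exhaustive) {
    res <- tryCatch(
      enumerate_table_extremes(r, cs,
        cap = if (method == "exhaustive") Inf else enum_cap),
      enumCap = function(e) NULL)
    if (!is.null(res)) {
      return(c(res, list(method = "exhaustive")))
    }
  }
  # heuristics tie-break by index, so canonicalize to sorted marginals:
  # the feasible table set (up to permutation) and hence the entropy
  # extremes depend only on the marginal multisets
  rs <- sort(as.numeric(r), decreasing = TRUE)
  css <- sort(as.numeric(cs), decreasing = TRUE)
  tmax <- most_even_table(rs, css)
  tmin <- most_concentrated_table(rs, css)
  list(H2max = shannon_entropy(tmax), H2min = shannon_entropy(tmin),
       method = "heuristic", table_max = tmax, table_min = tmin)
}

# Depth-first enumeration of all non-negative integer tables with the
# given marginals, tracking the entropy extremes. Cells are filled in
# row-major order; the last cell of each row and the last row are forced,
# and column capacity prunes the search.
enumerate_table_extremes <- function(r, cs, cap = Inf) {
  nr <- length(r)
  nc <- length(cs)
  best <- list(H2max = -Inf, H2min = Inf, table_max = NULL, table_min = NULL)
  count <- 0L
  tab <- matrix(0L, nr, nc)
  colrem <- as.integer(cs)
  fill_row <- function(i, j, rowrem) {
    if (j == nc) {
      if (rowrem > colrem[nc]) return()
      tab[i, nc] <<- rowrem
      colrem[nc] <<- colrem[nc] - rowrem
      if (i == nr) {
        count <<- count + 1L
        if (count > cap) {
          stop(structure(list(message = "enumeration cap exceeded",
                              call = NULL),
                         class = c("enumCap", "error", "condition")))
        }
        h <- shannon_entropy(tab)
        if (h > best$H2max) {
          best$H2max <<- h
          best$table_max <<- tab + 0L
        }
        if (h < best$H2min) {
          best$H2min <<- h
          best$table_min <<- tab + 0L
        }
      } else {
        fill_row(i + 1L, 1L, as.integer(r[i + 1L]))
      }
      colrem[nc] <<- colrem[nc] + rowrem
      return()
    }
    # feasibility: remaining cells of this row can absorb rowrem - v
    tail_cap <- sum(colrem[(j + 1L):nc])
    lo <- max(0L, rowrem - tail_cap)
    hi <- min(rowrem, colrem[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      tab[i, j] <<- v
      colrem[j] <<- colrem[j] - v
      fill_row(i, j + 1L, rowrem - v)
      colrem[j] <<- colrem[j] + v
    }
    tab[i, j] <<- 0L
  }
  fill_row(1L, 1L, as.integer(r[1L]))
  best[c("H2max", "H2min", "table_max", "table_min")]
}

# Most-even integer table honoring both marginals: floor of the
# independence expectations r_i c_j / F, then one-unit top-ups placed by
# largest fractional remainder (ties: smallest current cell, then lowest
# row, then lowest column index) among rows/columns still short.
most_even_table <- function(r, cs) {
  f <- sum(r)
  expect <- outer(r, cs) / f
  tab <- floor(expect)
  rr <- r - rowSums(tab)
  cc <- cs - colSums(tab)
  frac <- expect - tab
  while (sum(rr) > 0) {
    open <- outer(rr > 0, cc > 0, "&")
    if (!any(open)) stop("internal: even-table repair stuck")  # cannot happen
    score <- ifelse(open, frac, -Inf)
    cand <- which(score == max(score), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      vals <- tab[cand]
      cand <- cand[vals == min(vals), , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    tab[i, j] <- tab[i, j] + 1
    rr[i] <- rr[i] - 1
    cc[j] <- cc[j] - 1
  }
  tab
}

# Most-concentrated table: repeatedly place min(remaining row, remaining
# column) in the cell pairing the largest remaining marginals (ties:
# lowest row index, then lowest column index).
most_concentrated_table <- function(r, cs) {
  rr <- as.numeric(r)
  cc <- as.numeric(cs)
  tab <- matrix(0, length(r), length(cs))
  while (sum(rr) > 0) {
    i <- which.max(rr)
    j <- which.max(cc)
    amt <- min(rr[i], cc[j])
    tab[i, j] <- tab[i, j] + amt
    rr[i] <- rr[i] - amt
    cc[j] <- cc[j] - amt
  }
  tab
}
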
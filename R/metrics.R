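#' Connectance of a bipartite network
#'
#' Realized fraction of possible links, L / (R * A), computed on the
#' connected matrix (isolated species contribute no possible links by
#' construction, since they have no matrix row or column).
#'
#' @param net a `bipartite_network` or matrix.
#' @return connectance in (0, 1].
#' @export
connectance <- function(net) {
  w <- as_bipartite_network(net)$weights
  sum(w > 0) / (nrow(w) * ncol(w))
}

#' Number of links in a network
#'
#' @param net a `bipartite_network` or matrix.
#' @return count of positive cells.
#' @export
n_links <- function(net) {
  sum(as_bipartite_network(net)$weights > 0)
}

#' Links per species
#'
#' L / S, where S is the number of species. With
#' `include_isolated = TRUE` (the default) species observed in the
#' community but without interactions are counted in S, matching the
#' convention of reporting mean partners over all surveyed species.
#'
#' @param net a `bipartite_network`.
#' @param include_isolated count isolated species in S?
#' @return links-per-species ratio.
#' @export
links_per_species <- function(net, include_isolated = TRUE) {
  net <- as_bipartite_network(net)
  s <- nrow(net$weights) + ncol(net$weights) +
    if (include_isolated) length(net$isolated) else 0L
  n_links(net) / s
}

#' Unweighted degree of every species
#'
#' Number of interaction partners (positive cells) per species; isolated
#' species report degree 0.
#'
#' @param net a `bipartite_network`.
#' @return list with integer vectors `plants` and `pollinators`, named by
#'   species label (isolated species appended with degree 0).
#' @export
unweighted_degree <- function(net) {
  net <- as_bipartite_network(net)
  b <- net$weights > 0
  zeros <- function(lab) stats::setNames(rep(0L, length(lab)), lab)
  pl <- c(rowSums(b), zeros(net$isolated_plants))
  po <- c(colSums(b), zeros(net$isolated_pollinators))
  list(plants = stats::setNames(as.integer(pl), names(pl)),
       pollinators = stats::setNames(as.integer(po), names(po)))
}

#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' For every unordered pair of rows (and of columns) of the binary
#' matrix: the pair contributes 0 when the two marginal fills are equal
#' (no decreasing fill), otherwise the overlap count (shared positive
#' positions) divided by the smaller fill. NODF is the mean contribution
#' over all R(R-1)/2 + A(A-1)/2 pairs. The pairwise decreasing-fill
#' condition makes the value invariant to row/column order, so no
#' pre-sorting is performed.
#'
#' @param m binary matrix (or quantitative; positive cells are used)
#'   with no empty row or column.
#' @param scale `"unit"` (0--1, default) or `"percent"` (0--100).
#' @return NODF value.
#' @export
nodf <- function(m, scale = c("unit", "percent")) {
  scale <- match.arg(scale)
  b <- check_binary_input(m)
  val <- (nodf_pair_sum(b) + nodf_pair_sum(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
  if (scale == "percent") 100 * val else val
}

# sum of pairwise row contributions of a binary matrix (vectorized:
# overlap / smaller fill wherever the two fills differ)
nodf_pair_sum <- function(b) {
  n <- nrow(b)
  if (n < 2L) return(0)
  fills <- unname(rowSums(b))
  ov <- tcrossprod(b)               # shared positive positions
  minf <- outer(fills, fills, pmin)
  contrib <- ov / minf
  contrib[outer(fills, fills, "==")] <- 0
  sum(contrib[upper.tri(contrib)])
}

check_binary_input <- function(m) {
  if (inherits(m, "bipartite_network")) m <- m$weights
  m <- as.matrix(m)
  if (any(m < 0)) stop("matrix must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("matrix has an empty row or column")
  }
  (m > 0) + 0
}

#' Weighted NODF
#'
#' Quantitative analogue of [nodf()]: a pair of rows (columns)
#' contributes 0 unless their binary fills differ (decreasing fill);
#' otherwise the contribution is the fraction of positive cells in the
#' smaller-fill line whose paired cell in the larger-fill line is
#' strictly greater. Averaged over the same pair count as NODF. This is
#' the standard weighted-nestedness variant (a matrix with identical
#' rows scores 0, and binary input always scores 0).
#'
#' @param m non-negative quantitative matrix with no empty row/column.
#' @param scale `"unit"` or `"percent"`.
#' @return weighted NODF value.
#' @export
wnodf <- function(m, scale = c("unit", "percent")) {
  scale <- match.arg(scale)
  if (inherits(m, "bipartite_network")) m <- m$weights
  m <- as.matrix(m)
  check_binary_input(m)  # validity only
  val <- (wnodf_pair_sum(m) + wnodf_pair_sum(t(m))) /
    (choose(nrow(m), 2) + choose(ncol(m), 2))
  if (scale == "percent") 100 * val else val
}

wnodf_pair_sum <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(0)
  fills <- unname(rowSums(m > 0))
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (fills[i] == fills[j]) next
      hi <- if (fills[i] > fills[j]) i else j
      lo <- if (fills[i] > fills[j]) j else i
      pos <- m[lo, ] > 0
      s <- s + sum(m[hi, pos] > m[lo, pos]) / fills[lo]
    }
  }
  s
}

#' All basic network-level metrics at once
#'
#' @param net a `bipartite_network`.
#' @param nodf_scale scale passed to [nodf()] / [wnodf()].
#' @return list with `connectance`, `links`, `links_per_species`,
#'   `nodf`, `wnodf` and the [h2prime()] fragment.
#' @export
network_metrics <- function(net, nodf_scale = "unit") {
  net <- as_bipartite_network(net)
  c(list(connectance = connectance(net),
         links = n_links(net),
         links_per_species = links_per_species(net),
         nodf = nodf(net$weights, scale = nodf_scale),
         wnodf = wnodf(net$weights, scale = nodf_scale)),
    h2prime(net))
}
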
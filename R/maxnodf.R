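#' Effective link count for max-NODF analysis
#'
#' Maximum-NODF normalization requires the link count to be at least the
#' number of species (R + A), so that a binary matrix with no empty row
#' or column can realize every species. When a network falls short,
#' links are (conceptually) added: the default rule is
#' `L_eff = max(L, R + A)`; an explicit `links_added` override is
#' accepted so that published analyses that added a specific number of
#' links can be reproduced exactly.
#'
#' @param R,A matrix dimensions.
#' @param L observed (binary) link count; must be at least `max(R, A)`
#'   or no valid matrix exists.
#' @param links_added optional explicit number of links to add.
#' @return effective link count `L_eff`.
#' @export
augment_links <- function(R, A, L, links_added = NULL) {
  if (L < max(R, A)) {
    stop("no binary matrix with non-empty lines exists: L < max(R, A)")
  }
  l_eff <- if (!is.null(links_added)) L + links_added else max(L, R + A)
  if (l_eff > R * A) stop("L_eff exceeds the number of cells")
  l_eff
}

#' Maximum attainable NODF for a given shape and fill
#'
#' Finds the largest [nodf()] value over all R x A binary matrices with
#' exactly `L_eff` ones and no empty row or column. Small problems are
#' solved exactly by enumerating every placement of the ones;
#' larger ones by a greedy nested fill followed by steepest-ascent
#' one-swap hill climbing with random restarts.
#'
#' @param R,A matrix dimensions.
#' @param L_eff number of ones; `max(R, A) <= L_eff <= R * A`.
#' @param method `"auto"` (exhaustive when `choose(R*A, L_eff) <= 1e6`),
#'   `"exhaustive"` or `"heuristic"`.
#' @param restarts hill-climbing restarts for the heuristic (default 50).
#' @param seed RNG seed for the heuristic restarts (default 1).
#' @return object of class `max_nodf_result`: `R`, `A`, `L_eff`,
#'   `max_nodf` (0--1 scale), `witness` binary matrix, `method` used,
#'   `links_added` (0 here; filled by callers that augmented).
#' @export
max_nodf <- function(R, A, L_eff, method = c("auto", "exhaustive", "heuristic"),
                     restarts = 50, seed = 1) {
  method <- match.arg(method)
  if (L_eff < max(R, A) || L_eff > R * A) {
    stop("infeasible link count for a matrix with no empty row or column")
  }
  n_place <- choose(R * A, L_eff)
  if (method == "auto") {
    method <- if (n_place <= 1e6) "exhaustive" else "heuristic"
  }
  if (method == "exhaustive") {
    if (n_place > 1e6) stop("exhaustive search infeasible: ",
                            format(n_place), " placements")
    res <- max_nodf_exhaustive(R, A, L_eff)
  } else {
    res <- max_nodf_heuristic(R, A, L_eff, restarts = restarts, seed = seed)
  }
  structure(
    list(R = R, A = A, L_eff = L_eff, max_nodf = res$value,
         witness = res$witness, method = method, links_added = 0L),
    class = "max_nodf_result")
}

max_nodf_exhaustive <- function(R, A, L_eff) {
  best <- -Inf
  witness <- NULL
  m <- matrix(0L, R, A)
  utils::combn(R * A, L_eff, FUN = function(cells) {
    m[] <- 0L
    m[cells] <- 1L
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(invisible(NULL))
    v <- nodf(m)
    if (v > best) {
      best <<- v
      witness <<- m + 0L
    }
    invisible(NULL)
  }, simplify = FALSE)
  list(value = best, witness = witness)
}

max_nodf_heuristic <- function(R, A, L_eff, restarts = 50, seed = 1) {
  set.seed(as.integer(seed))
  best <- -Inf
  witness <- NULL
  for (r in seq_len(restarts)) {
    m <- if (r == 1L) greedy_nested_fill(R, A, L_eff) else
      random_valid_fill(R, A, L_eff)
    m <- hill_climb_nodf(m)
    v <- nodf(m)
    if (v > best) {
      best <- v
      witness <- m
    }
  }
  list(value = best, witness = witness)
}

# deterministic nested seed: prefix-supported rows (row i occupies the
# first f_i columns) with fills as strictly decreasing as the budget
# allows -- a perfect subset chain whenever one with L_eff ones exists
greedy_nested_fill <- function(R, A, L_eff) {
  f <- integer(R)
  rem <- L_eff
  for (i in seq_len(R)) {
    cap <- if (i == 1L) A else max(1L, f[i - 1L] - 1L)
    f[i] <- max(1L, min(cap, rem - (R - i)))
    rem <- rem - f[i]
  }
  # strict decrease may underspend; top up keeping fills non-increasing
  while (rem > 0) {
    for (i in seq_len(R)) {
      cap <- if (i == 1L) A else f[i - 1L]
      add <- min(cap - f[i], rem)
      f[i] <- f[i] + add
      rem <- rem - add
      if (rem == 0L) break
    }
  }
  m <- matrix(0L, R, A)
  for (i in seq_len(R)) m[i, seq_len(f[i])] <- 1L
  repair_coverage(m, L_eff)  # trailing columns can be empty when f_1 < A
  }

random_valid_fill <- function(R, A, L_eff) {
  m <- matrix(0L, R, A)
  # cover all rows and columns first with a random perfect "spread"
  cols <- sample(c(seq_len(A), sample.int(A, max(0L, R - A), replace = TRUE)))
  m[cbind(seq_len(R), cols[seq_len(R)])] <- 1L
  for (j in which(colSums(m) == 0)) m[sample.int(R, 1L), j] <- 1L
  need <- L_eff - sum(m)
  if (need > 0) {
    empty <- which(m == 0L)
    m[sample(empty, need)] <- 1L
  }
  m
}

# steepest-ascent: move one 1 to an empty cell (keeping all lines
# non-empty) while NODF improves
hill_climb_nodf <- function(m) {
  repeat {
    cur <- nodf(m)
    filled <- which(m == 1L, arr.ind = TRUE)
    empty <- which(m == 0L, arr.ind = TRUE)
    if (nrow(empty) == 0L) return(m)
    best_gain <- 0
    best_move <- NULL
    rs <- rowSums(m)
    cs <- colSums(m)
    for (fi in seq_len(nrow(filled))) {
      i <- filled[fi, 1]; j <- filled[fi, 2]
      if (rs[i] == 1L || cs[j] == 1L) next  # removal would empty a line
      m[i, j] <- 0L
      for (ei in seq_len(nrow(empty))) {
        m[empty[ei, 1], empty[ei, 2]] <- 1L
        v <- nodf(m)
        if (v - cur > best_gain + 1e-12) {
          best_gain <- v - cur
          best_move <- c(i, j, empty[ei, 1], empty[ei, 2])
        }
        m[empty[ei, 1], empty[ei, 2]] <- 0L
      }
      m[i, j] <- 1L
    }
    if (is.null(best_move)) return(m)
    m[best_move[1], best_move[2]] <- 0L
    m[best_move[3], best_move[4]] <- 1L
  }
}

#' Combined (size-corrected) nestedness NODF_c
#'
#' Normalizes raw NODF by the maximum NODF attainable at the same shape
#' and link count, then corrects for connectance and network size:
#' `NODF_c = (raw / max) / (C * log10(sqrt(R * A)))`, with connectance
#' `C = L_original / (R * A)` computed from the ORIGINAL link count
#' (before any augmentation used to make max NODF computable). This
#' makes nestedness comparable across networks of different dimensions.
#'
#' @param raw_nodf,max_nodf raw and maximum NODF on a common scale
#'   (both unit or both percent; the ratio cancels the scale).
#' @param R,A network dimensions.
#' @param L_original observed link count (>= 1).
#' @return list with `raw_nodf`, `max_nodf`, `connectance`, `nodf_c`.
#' @export
nodf_c <- function(raw_nodf, max_nodf, R, A, L_original) {
  if (L_original < 1) stop("L_original must be at least 1")
  cval <- L_original / (R * A)
  if (raw_nodf == 0) {
    # un-nested network: NODF_c is 0 regardless of the (possibly also
    # zero, e.g. for a completely filled matrix) maximum
    return(list(raw_nodf = 0, max_nodf = max_nodf, connectance = cval,
                nodf_c = 0))
  }
  if (max_nodf <= 0) stop("max_nodf must be positive")
  list(raw_nodf = raw_nodf, max_nodf = max_nodf, connectance = cval,
       nodf_c = (raw_nodf / max_nodf) / (cval * log10(sqrt(R * A))))
}

#' Compare nestedness across a series of daily networks
#'
#' Computes, for each dated network (or row of pre-computed parameters),
#' raw NODF, the maximum NODF at the same shape and effective link
#' count, and the combined nestedness NODF_c, and identifies the day
#' with the highest NODF_c.
#'
#' @param series either a named list of `bipartite_network` objects /
#'   binary matrices (names = day labels), or a data.frame with columns
#'   `day`, `R`, `A`, `L`, `raw_nodf`, `max_nodf` (pre-computed
#'   parameters, e.g. from a published table) in which case only NODF_c
#'   is derived.
#' @param links_added optional named vector of per-day link-addition
#'   overrides (passed to [augment_links()]).
#' @param method,restarts,seed forwarded to [max_nodf()].
#' @return data.frame (one row per day) with columns `day`, `R`, `A`,
#'   `L`, `links_added`, `raw_nodf`, `max_nodf`, `nodf_c`; attribute
#'   `best_day` holds the argmax day label.
#' @export
compare_daily <- function(series, links_added = NULL,
                          method = "auto", restarts = 50, seed = 1) {
  if (is.data.frame(series)) {
    out <- series[, c("day", "R", "A", "L", "raw_nodf", "max_nodf")]
    out$links_added <- if (is.null(links_added)) 0L else
      as.integer(links_added[as.character(out$day)])
    out$nodf_c <- mapply(function(raw, mx, R, A, L)
      nodf_c(raw, mx, R, A, L)$nodf_c,
      out$raw_nodf, out$max_nodf, out$R, out$A, out$L)
  } else {
    days <- names(series)
    if (is.null(days)) days <- as.character(seq_along(series))
    rows <- lapply(seq_along(series), function(k) {
      w <- as_bipartite_network(series[[k]])$weights
      b <- (w > 0) + 0
      R <- nrow(b); A <- ncol(b); L <- sum(b)
      add <- if (!is.null(links_added) && days[k] %in% names(links_added)) {
        links_added[[days[k]]]
      } else NULL
      l_eff <- augment_links(R, A, L, links_added = add)
      mx <- max_nodf(R, A, l_eff, method = method, restarts = restarts,
                     seed = seed)
      raw <- nodf(b)
      data.frame(day = days[k], R = R, A = A, L = L,
                 links_added = l_eff - L, raw_nodf = raw,
                 max_nodf = mx$max_nodf,
                 nodf_c = nodf_c(raw, mx$max_nodf, R, A, L)$nodf_c,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  structure(out, best_day = out$day[which.max(out$nodf_c)])
}
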
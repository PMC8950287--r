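#' Build a quantitative bipartite network from visitation records
#'
#' Aggregates long-format visitation records (one row per observed
#' plant--pollinator visit bout, with a visit count) into a quantitative
#' interaction matrix. Species whose total visit count is zero after
#' aggregation are not given a matrix row or column; they are kept on an
#' isolated-species register so that network-level summaries can still
#' report them (a plant that flowered but received no visits has degree 0
#' but must not create an empty matrix line).
#'
#' @param records data.frame with columns `day` (integer Julian day of
#'   year, 1--366), `plant` (character), `pollinator` (character) and
#'   `visits` (non-negative integer).
#' @param day_filter optional integer vector; only records whose `day` is
#'   in this set are used.
#' @param sort_labels if `TRUE`, row/column labels are sorted
#'   lexicographically; default keeps first-appearance order. All metrics
#'   in this package are invariant to this choice.
#' @return an object of class `bipartite_network`: a list with `weights`
#'   (labelled R x A integer matrix, every line has a positive entry),
#'   `plants`, `pollinators` (label vectors) and `isolated` (labels seen
#'   in the records but with zero aggregate visits).
#' @examples
#' rec <- data.frame(day = 147, plant = c("p1", "p1"),
#'                   pollinator = c("a1", "a1"), visits = c(2, 1))
#' net <- build_network(rec)
#' net$weights   # 1 x 1 matrix, value 3
#' @export
build_network <- function(records, day_filter = NULL, sort_labels = FALSE) {
  records <- validate_records(records)
  if (!is.null(day_filter)) {
    records <- records[records$day %in% day_filter, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no interaction records remain after filtering: empty network")
  }
  plants <- unique(records$plant)
  polls <- unique(records$pollinator)
  if (sort_labels) {
    plants <- sort(plants)
    polls <- sort(polls)
  }
  w <- matrix(0L, nrow = length(plants), ncol = length(polls),
              dimnames = list(plants, polls))
  for (r in seq_len(nrow(records))) {
    w[records$plant[r], records$pollinator[r]] <-
      w[records$plant[r], records$pollinator[r]] + records$visits[r]
  }
  isolated_p <- plants[rowSums(w) == 0]
  isolated_a <- polls[colSums(w) == 0]
  w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  if (nrow(w) == 0L || ncol(w) == 0L) {
    stop("all records have zero visits: empty network")
  }
  new_bipartite_network(w, isolated_plants = isolated_p,
                        isolated_pollinators = isolated_a)
}

validate_records <- function(records) {
  req <- c("day", "plant", "pollinator", "visits")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  }
  records$plant <- as.character(records$plant)
  records$pollinator <- as.character(records$pollinator)
  if (any(!nzchar(records$plant)) || any(!nzchar(records$pollinator))) {
    stop("species labels must be non-empty strings")
  }
  if (any(is.na(records$visits)) || any(records$visits < 0) ||
      any(records$visits != as.integer(records$visits))) {
    stop("visits must be non-negative integers")
  }
  if (any(is.na(records$day)) || any(records$day < 1) ||
      any(records$day > 366)) {
    stop("day must be a Julian day of year in [1, 366]")
  }
  records$visits <- as.integer(records$visits)
  records$day <- as.integer(records$day)
  records
}

new_bipartite_network <- function(weights, isolated_plants = character(),
                                  isolated_pollinators = character()) {
  stopifnot(is.matrix(weights), nrow(weights) >= 1L, ncol(weights) >= 1L)
  if (is.null(dimnames(weights))) {
    dimnames(weights) <- list(paste0("p", seq_len(nrow(weights))),
                              paste0("a", seq_len(ncol(weights))))
  }
  if (any(weights < 0)) stop("interaction weights must be non-negative")
  if (any(rowSums(weights) == 0) || any(colSums(weights) == 0)) {
    stop("every matrix row and column must have at least one interaction")
  }
  structure(
    list(weights = weights,
         plants = rownames(weights),
         pollinators = colnames(weights),
         isolated_plants = as.character(isolated_plants),
         isolated_pollinators = as.character(isolated_pollinators),
         isolated = c(as.character(isolated_plants),
                      as.character(isolated_pollinators))),
    class = "bipartite_network")
}

#' Coerce a plain matrix to a bipartite_network
#'
#' @param m non-negative matrix with no empty row or column; dimnames are
#'   used as species labels if present.
#' @param isolated_plants,isolated_pollinators optional labels of species
#'   observed in the community but with zero interactions.
#' @return a `bipartite_network`.
#' @export
as_bipartite_network <- function(m, isolated_plants = character(),
                                 isolated_pollinators = character()) {
  if (inherits(m, "bipartite_network")) return(m)
  new_bipartite_network(as.matrix(m), isolated_plants = isolated_plants,
                        isolated_pollinators = isolated_pollinators)
}

#' Reduce a network to binary (presence/absence) weights
#'
#' @param net a `bipartite_network` or matrix.
#' @return a `bipartite_network` whose weights are 0/1; the number of
#'   links is unchanged.
#' @export
to_binary <- function(net) {
  net <- as_bipartite_network(net)
  w <- net$weights
  w[] <- as.integer(w > 0)
  new_bipartite_network(w, isolated_plants = net$isolated_plants,
                        isolated_pollinators = net$isolated_pollinators)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d plants x %d pollinators, %d links, total weight %d\n",
              nrow(x$weights), ncol(x$weights),
              sum(x$weights > 0), sum(x$weights)))
  if (length(x$isolated)) {
    cat("isolated species:", paste(x$isolated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read long-format visitation records from CSV
#'
#' Expects the header `day,plant,pollinator,visits`. Rows failing
#' validation produce an error naming the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of validated interaction records (possibly 0 rows).
#' @export
read_interactions_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character"),
                        stringsAsFactors = FALSE)
  req <- c("day", "plant", "pollinator", "visits")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("interaction CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- df[, req]
  if (nrow(df) == 0L) {
    return(data.frame(day = integer(), plant = character(),
                      pollinator = character(), visits = integer(),
                      stringsAsFactors = FALSE))
  }
  parse_int <- function(x, col) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) | v != floor(v) | (col == "visits" & v < 0))
    if (length(bad)) {
      stop(sprintf("invalid %s value %s at data row %d", col,
                   dQuote(x[bad[1]]), bad[1]))
    }
    as.integer(v)
  }
  out <- data.frame(day = parse_int(df$day, "day"),
                    plant = df$plant,
                    pollinator = df$pollinator,
                    visits = parse_int(df$visits, "visits"),
                    stringsAsFactors = FALSE)
  validate_records(out)
}

#' Write visitation records to CSV
#'
#' Round-trips bit-exactly with [read_interactions_csv()].
#'
#' @param records validated records data.frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_interactions_csv <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records[, c("day", "plant", "pollinator", "visits")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a quantitative interaction matrix as TSV
#'
#' Layout: first row holds pollinator labels, first column plant labels,
#' integer cells.
#'
#' @param path TSV file path.
#' @return `read_matrix_tsv`: a `bipartite_network`.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  new_bipartite_network(m)
}

#' @param net a `bipartite_network` or matrix.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(net, path) {
  net <- as_bipartite_network(net)
  utils::write.table(net$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Flatten a network back to long-format records
#'
#' @param net a `bipartite_network`.
#' @param day Julian day to stamp on every record.
#' @return records data.frame (one row per positive cell).
#' @export
network_to_records <- function(net, day = 1L) {
  net <- as_bipartite_network(net)
  idx <- which(net$weights > 0, arr.ind = TRUE)
  data.frame(day = as.integer(day),
             plant = rownames(net$weights)[idx[, 1]],
             pollinator = colnames(net$weights)[idx[, 2]],
             visits = as.integer(net$weights[idx]),
             stringsAsFactors = FALSE)
}
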
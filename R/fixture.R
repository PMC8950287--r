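#' Load the packaged survey-tables fixture
#'
#' Returns the published summary tables of the *Cypripedium guttatum*
#' pollination survey exactly as printed: species lists, unweighted
#' degree sequences and centrality scores for both trophic levels,
#' visitation-bout durations, hourly visit counts of the effective
#' pollinator, flowering dates, and the per-day parameters of the daily
#' nestedness comparison. The quantitative interaction matrix was never
#' published, so everything matrix-dependent in this package is either
#' derived from these summaries or demonstrated on a synthetic
#' realization (see [fixture_network()]).
#'
#' @return object of class `survey_fixture` (a named list mirroring the
#'   JSON shipped in `inst/extdata/survey_tables.json`, with
#'   `daily_params` as a data.frame and `hourly_visits` as a labelled
#'   matrix).
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "survey_tables.json", package = "pollinet",
                      mustWork = TRUE)
  fx <- jsonlite::fromJSON(path)
  fx$plant_degrees <- stats::setNames(as.integer(fx$plant_degrees),
                                      fx$plant_species)
  fx$pollinator_degrees <- stats::setNames(as.integer(fx$pollinator_degrees),
                                           fx$pollinator_species)
  hv <- as.matrix(fx$hourly_visits)   # fromJSON yields a dates x windows matrix
  storage.mode(hv) <- "integer"
  dimnames(hv) <- list(fx$hourly_dates, fx$hourly_windows)
  fx$hourly_visits <- hv
  fx$daily_params <- as.data.frame(fx$daily_params)
  class(fx) <- "survey_fixture"
  fx
}

#' @export
print.survey_fixture <- function(x, ...) {
  cat(sprintf(
    "survey_fixture: %d plants, %d pollinators, %d links (degree sums)\n",
    length(x$plant_species), length(x$pollinator_species),
    sum(x$pollinator_degrees)))
  invisible(x)
}

#' Centrality tables of the fixture, in `centrality_table` layout
#'
#' @param fx a `survey_fixture` (default: [load_fixture()]).
#' @return data.frame with `species`, `level`, `degree`, `bc`, `cc` for
#'   all 31 surveyed species (isolated species carry `NA` centralities).
#' @export
fixture_centrality_table <- function(fx = load_fixture()) {
  data.frame(
    species = c(fx$plant_species, fx$pollinator_species),
    level = c(rep("plant", length(fx$plant_species)),
              rep("pollinator", length(fx$pollinator_species))),
    degree = c(unname(fx$plant_degrees), unname(fx$pollinator_degrees)),
    bc = c(fx$plant_bc, fx$pollinator_bc),
    cc = c(fx$plant_cc, fx$pollinator_cc),
    stringsAsFactors = FALSE)
}

#' Synthetic realization of the surveyed network
#'
#' The published record gives the degree of every species but not the
#' interaction matrix. This helper builds ONE binary matrix consistent
#' with the printed degree sequences (a seeded Gale-Ryser realization;
#' one of many consistent matrices, NOT the observed network) and wraps
#' it as a `bipartite_network` with the zero-degree plant on the
#' isolated register. Use it for demonstrations and for metrics that
#' depend only on the degree sequences (connectance, link counts,
#' degrees); never treat matrix-dependent metrics computed on it as
#' estimates of the real network.
#'
#' @param fx a `survey_fixture`.
#' @param seed RNG seed for the realization (default 1, the seed used
#'   for the CSV shipped in `inst/extdata/interactions_synthetic.csv`).
#' @return a `bipartite_network` with 11 plants, 19 pollinators,
#'   42 links, and the zero-degree plant isolated.
#' @export
fixture_network <- function(fx = load_fixture(), seed = 1) {
  rl <- realize_degree_sequence(fx$plant_degrees, fx$pollinator_degrees,
                                seed = seed)
  if (!isTRUE(rl$feasible)) {
    stop("fixture degree sequences are infeasible: ", rl$reason)
  }
  as_bipartite_network(
    rl$matrix,
    isolated_plants = names(fx$plant_degrees)[fx$plant_degrees == 0])
}

#' Path to the shipped synthetic interaction CSV
#'
#' Long-format records of the seed-1 [fixture_network()] realization
#' (one visit per realized link, plus a zero-visit record that keeps the
#' unvisited plant on the register). A reconstruction for examples and
#' tests, not field data.
#'
#' @return file path.
#' @export
fixture_interactions_csv <- function() {
  system.file("extdata", "interactions_synthetic.csv", package = "pollinet",
              mustWork = TRUE)
}
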
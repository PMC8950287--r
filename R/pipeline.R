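#' Default pipeline configuration
#'
#' Defaults mirror the analysis conventions of the survey this package
#' reproduces: 1000 fixed-marginal null networks, 95% central band, 100
#' modularity repetitions. `n_random_q` and `q_repetitions_null`
#' control the (expensive) modularity null ensemble separately so it
#' can be scaled down.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_random null networks for NODF and H2' ensembles.
#' @param n_random_q null networks for the Q ensemble.
#' @param repetitions annealing repetitions for the observed network.
#' @param q_repetitions_null annealing repetitions per null network.
#' @param steps annealing moves per repetition.
#' @param include_daily compute the per-day NODF_c table when records
#'   span several days.
#' @return named list of settings.
#' @export
pipeline_config <- function(seed = 1, n_random = 1000, n_random_q = 100,
                            repetitions = 100, q_repetitions_null = 3,
                            steps = 1e4, include_daily = TRUE) {
  list(seed = seed, n_random = n_random, n_random_q = n_random_q,
       repetitions = repetitions, q_repetitions_null = q_repetitions_null,
       steps = steps, include_daily = include_daily)
}

#' Run the full network-analysis pipeline
#'
#' Orchestrates every stage of the community pollination analysis on
#' one set of visitation records: network construction, basic metrics
#' (connectance, links per species, NODF, weighted NODF, H2'),
#' fixed-marginal null-model significance for NODF, H2' and Q,
#' module detection, centrality-based keystone ranking per trophic
#' level, and (when the records span several days) the per-day
#' max-NODF-normalized nestedness comparison.
#'
#' @param records interaction records data.frame (see
#'   [build_network()]) or a path to an interaction CSV.
#' @param config list from [pipeline_config()].
#' @param quiet suppress per-stage progress messages (stderr)?
#' @return object of class `analysis_report` (nested list with
#'   `network`, `metrics`, `nulls`, `modules`, `centrality`,
#'   `keystones`, `daily`, `provenance`).
#' @export
run_pipeline <- function(records, config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[pollinet] ", sprintf(...))
  if (is.character(records)) records <- read_interactions_csv(records)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say("building network from %d records", nrow(records))
  net <- stage("build_network", build_network(records))
  say("computing network-level metrics")
  metrics <- stage("metrics", network_metrics(net))
  say("null models: NODF and H2' (%d nulls), Q (%d nulls)",
      config$n_random, config$n_random_q)
  seeds <- config$seed + 0:3
  nulls <- stage("null_models", list(
    nodf = null_test(net, function(m) nodf(m), n_random = config$n_random,
                     seed = seeds[1], metric_name = "nodf"),
    h2prime = null_test(net, function(m) h2prime(m)$h2prime,
                        n_random = config$n_random, seed = seeds[2],
                        metric_name = "h2prime"),
    Q = null_test(net, function(m) find_modules(
          m, n_repetitions = config$q_repetitions_null,
          steps = config$steps, seed = seeds[3])$Q,
        n_random = config$n_random_q, seed = seeds[3],
        metric_name = "Q")))
  say("module detection (%d repetitions)", config$repetitions)
  modules <- stage("modules", find_modules(
    net, n_repetitions = config$repetitions, steps = config$steps,
    seed = seeds[4]))
  say("centralities and keystone ranking")
  cent <- stage("centrality", centralities(net))
  keystones <- stage("keystones", list(
    pollinator = keystone_rank(cent, "pollinator"),
    plant = keystone_rank(cent, "plant")))
  daily <- NULL
  days <- sort(unique(records$day[records$visits > 0]))
  if (config$include_daily && length(days) > 1L) {
    say("daily nestedness comparison over %d days", length(days))
    series <- lapply(days, function(d) build_network(records, day_filter = d))
    names(series) <- as.character(days)
    daily <- stage("daily", compare_daily(series, seed = config$seed))
  }
  structure(
    list(network = net, metrics = metrics, nulls = nulls,
         modules = modules, centrality = cent, keystones = keystones,
         daily = daily,
         provenance = list(
           seed = config$seed, stage_seeds = seeds, config = config,
           package_version = as.character(utils::packageVersion("pollinet")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  m <- x$metrics
  cat("analysis_report\n")
  cat(sprintf("  network: %d plants x %d pollinators, %d links (+%d isolated)\n",
              nrow(x$network$weights), ncol(x$network$weights), m$links,
              length(x$network$isolated)))
  cat(sprintf("  connectance %.3f | links/species %.2f | NODF %.3f | H2' %.3f\n",
              m$connectance, m$links_per_species, m$nodf, m$h2prime))
  for (nm in names(x$nulls)) {
    nl <- x$nulls[[nm]]
    cat(sprintf("  %-8s observed %.3f vs null [%.3f, %.3f] -> %s\n",
                nm, nl$observed, nl$ci_low, nl$ci_high,
                if (nl$significant) "significant" else "not significant"))
  }
  cat(sprintf("  modules: %d (Q = %.3f)\n", x$modules$n_modules, x$modules$Q))
  cat(sprintf("  keystone pollinator: %s | keystone plant: %s\n",
              x$keystones$pollinator$species[1], x$keystones$plant$species[1]))
  if (!is.null(x$daily)) {
    cat(sprintf("  daily NODF_c: best day %s\n", attr(x$daily, "best_day")))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic serialization (stable key order, full precision):
#' rerunning the pipeline with identical config and seeds reproduces
#' the file byte-for-byte. Null-sample vectors are summarized by their
#' CI bounds; set `keep_samples = TRUE` to embed them.
#'
#' @param report an `analysis_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @param keep_samples embed full null-sample vectors?
#' @return JSON string (invisibly, when `path` is given).
#' @export
report_to_json <- function(report, path = NULL, keep_samples = FALSE) {
  null_block <- function(nl) {
    out <- list(metric = nl$metric, observed = nl$observed,
                n_random = nl$n_random, ci_low = nl$ci_low,
                ci_high = nl$ci_high, significant = nl$significant,
                seed = nl$seed)
    if (keep_samples) out$samples <- nl$samples
    out
  }
  obj <- list(
    network = list(
      plants = report$network$plants,
      pollinators = report$network$pollinators,
      isolated = report$network$isolated,
      weights = unname(apply(report$network$weights, 1, as.integer,
                             simplify = FALSE))),
    metrics = report$metrics,
    nulls = lapply(report$nulls, null_block),
    modules = list(
      Q = report$modules$Q, n_modules = report$modules$n_modules,
      assignment = as.list(report$modules$assignment),
      seed = report$modules$seed),
    centrality = as.data.frame(report$centrality),
    keystones = list(
      pollinator = report$keystones$pollinator,
      plant = report$keystones$plant),
    daily = if (!is.null(report$daily)) {
      list(table = as.data.frame(report$daily),
           best_day = attr(report$daily, "best_day"))
    },
    provenance = report$provenance[c("seed", "stage_seeds",
                                     "package_version")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
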
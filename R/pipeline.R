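#' Run the full surveillance report
#'
#' Executes the whole pipeline on a validated audit: category breakdown
#' (n (%) per category, optionally per group), per-country / per-ingredient
#' prevalence and cumulative-CTR exposure, redirection-network construction
#' with per-node metrics and whole-network statistics, destination-profile
#' joins (legitimacy, visitor totals), graph exports, and a run manifest
#' whose config hash changes whenever any output-affecting parameter
#' changes. All analysis stages are deterministic; randomness lives only in
#' the synthetic generator.
#'
#' @param records Validated audit tibble (real or synthetic).
#' @param model A [rank_ctr_model()] covering the audit's rank range.
#' @param profiles Optional destination-profile tibble (domain, legitimacy,
#'   monthly_unique_visitors).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing and return the bundle only.
#' @param group_by Grouping for the exposure table.
#' @param breakdown_by Grouping for the category table.
#' @param top_k Hub-concentration k for [network_stats()].
#' @param damping,tol,max_iter PageRank parameters.
#' @param seed Seed recorded in the manifest (for synthetic inputs).
#' @param quiet Suppress per-stage log messages.
#' @return A report bundle (list): breakdown, exposure, network, metrics,
#'   stats, visitors, manifest.
#' @export
run_report <- function(records, model = rank_ctr_model(),
                       profiles = NULL, out_dir = NULL,
                       group_by = c("country", "api"),
                       breakdown_by = character(),
                       top_k = 3L, damping = 0.85, tol = 1e-9,
                       max_iter = 1000L, seed = NULL, quiet = FALSE) {
  log_info <- function(...) if (!quiet) message("INFO: ", sprintf(...))
  n_eval <- sum(!records$excluded)
  n_comp <- sum(records$category %in% compromised_categories() & !records$excluded)
  n_act <- sum(records$category == "active_redirect" & !records$excluded)
  log_info("records: %d documented, %d excluded, %d evaluated, %d compromised, %d active",
           nrow(records), sum(records$excluded), n_eval, n_comp, n_act)

  breakdown <- tabulate_categories(records, group_by = breakdown_by)
  log_info("category breakdown: %d rows", nrow(breakdown))

  exposure <- exposure_report(records, model, group_by = group_by)
  log_info("exposure table: %d groups", nrow(exposure))

  net <- build_network(records[!records$excluded, , drop = FALSE])
  stats_tbl <- network_stats(net, k = top_k)
  metrics <- if (igraph::vcount(net) > 0) {
    node_metrics(net, damping = damping, tol = tol, max_iter = max_iter)
  } else {
    tibble::tibble(domain = character(), role = character(),
                   in_degree = numeric(), distinct_sources = numeric(),
                   pagerank = numeric())
  }
  log_info("network: %d nodes, %d edges, %d destinations",
           stats_tbl$n_nodes, stats_tbl$n_edges, stats_tbl$n_destinations)

  visitors <- NULL
  if (!is.null(profiles)) {
    dest_doms <- metrics$domain[metrics$role %in% c("destination", "both")]
    joined <- profiles[profiles$domain %in% dest_doms, , drop = FALSE]
    visitors <- aggregate_visitors(joined, require_pharmacy_named = TRUE)
    log_info("visitor aggregation: %d domains summed, total %s",
             visitors$n_included, format(visitors$total, big.mark = ","))
  }

  manifest <- list(
    package = "serpnet",
    version = as.character(utils::packageVersion("serpnet")),
    seed = seed,
    n_records = nrow(records),
    n_evaluated = n_eval,
    n_compromised = n_comp,
    n_active = n_act,
    parameters = list(
      model = unclass(model), group_by = group_by, breakdown_by = breakdown_by,
      top_k = top_k, damping = damping, tol = tol, max_iter = max_iter
    )
  )
  manifest$config_hash <- rlang::hash(manifest$parameters)

  bundle <- list(breakdown = breakdown, exposure = exposure, network = net,
                 metrics = metrics, stats = stats_tbl, visitors = visitors,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(render_breakdown(breakdown),
                     file.path(out_dir, "category_breakdown.csv"), progress = FALSE)
    write_breakdown_json(breakdown, file.path(out_dir, "category_breakdown.json"))
    readr::write_csv(exposure, file.path(out_dir, "exposure.csv"), progress = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "node_metrics.csv"), progress = FALSE)
    readr::write_csv(stats_tbl, file.path(out_dir, "network_stats.csv"), progress = FALSE)
    if (igraph::vcount(net) > 0) {
      export_graph(net, file.path(out_dir, "redirection_network.graphml"),
                   "graphml", metrics = metrics, profiles = profiles)
      export_graph(net, file.path(out_dir, "redirection_network.gexf"),
                   "gexf", metrics = metrics, profiles = profiles)
      export_graph(net, file.path(out_dir, "redirection_edges.csv"),
                   "edge_csv", metrics = metrics, profiles = profiles)
    }
    if (!is.null(visitors)) {
      readr::write_csv(visitors$included, file.path(out_dir, "visitor_coverage.csv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log_info("report bundle written to %s", out_dir)
  }
  invisible(bundle)
}
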
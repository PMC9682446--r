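#!/usr/bin/env Rscript
# Reconstruct the redirection network from active redirects: per-node
# in-degree / PageRank, hub concentration, per-source affiliate structure,
# legitimacy and traffic joins, and Gephi-compatible exports.

suppressPackageStartupMessages(library(serpnet))

audit <- read_audit("results/synthetic_audit.csv", rank_max = 40)
profiles <- readr::read_csv("results/destination_profiles.csv",
                            show_col_types = FALSE)

net <- build_network(audit)
metrics <- node_metrics(net)
stats <- network_stats(net, k = 3)
readr::write_csv(metrics, "results/node_metrics.csv")
readr::write_csv(stats, "results/network_stats.csv")

message(sprintf("network: %d nodes, %d edges, %d destinations, average degree %.3f",
                stats$n_nodes, stats$n_edges, stats$n_destinations,
                stats$average_degree))
message(sprintf("top-3 destinations receive %.1f%% of all %d incoming links; %.0f%% of destinations get only 1-2",
                100 * stats$top_k_share, stats$total_links,
                100 * stats$low_degree_share))

hubs <- metrics[metrics$role == "destination", ][1:5, ]
print(hubs)

src <- source_summary(audit)
readr::write_csv(src, "results/source_summary.csv")
message(sprintf("sources: %d; single-destination %.1f%%, multi-ingredient %.1f%%, mean fan-out %.2f",
                nrow(src), 100 * mean(src$single_destination),
                100 * mean(src$multi_api), mean(src$n_destinations)))

dest_profiles <- profiles[profiles$domain %in%
                            metrics$domain[metrics$role != "source"], ]
agg <- aggregate_visitors(dest_profiles, require_pharmacy_named = TRUE)
message(sprintf("monthly unique visitors over %d pharmacy-named destinations with traffic data: %s (no data: %d domains)",
                agg$n_included, format(agg$total, big.mark = ","),
                length(agg$missing_visitors)))

export_graph(net, "results/redirection_network.graphml", "graphml",
             metrics = metrics, profiles = profiles)
export_graph(net, "results/redirection_network.gexf", "gexf",
             metrics = metrics, profiles = profiles)
export_graph(net, "results/redirection_edges.csv", "edge_csv",
             metrics = metrics, profiles = profiles)
message("graph exports written (GraphML, GEXF, edge CSV)")
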
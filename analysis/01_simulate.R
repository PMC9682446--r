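#!/usr/bin/env Rscript
# Generate the synthetic multi-country SERP audit and destination profiles
# that the downstream analysis steps consume. The generator defaults encode
# the study shape: 12 countries x 4 active ingredients x top-40 results
# (1920 evaluated links), ~19.8% compromised, hub-dominated affiliate
# network over 73 candidate destinations.

suppressPackageStartupMessages(library(serpnet))

seed <- 20201115L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
audit <- generate_audit(cfg)
profiles <- generate_destination_profiles(cfg)

write_audit(audit, "results/synthetic_audit.csv")
readr::write_csv(profiles, "results/destination_profiles.csv")

message(sprintf("simulated %d search results across %d countries, seed %d",
                nrow(audit), length(cfg$countries), seed))
message(sprintf("compromised: %d (%.1f%%), active redirects: %d",
                sum(audit$category %in% compromised_categories()),
                100 * mean(audit$category %in% compromised_categories()),
                sum(audit$category == "active_redirect")))

# a second snapshot one survival-median later, to study the life cycle
later <- evolve_snapshot(audit, cfg$survival_median_days)
write_audit(later, "results/synthetic_audit_t19d.csv")
message(sprintf("evolved snapshot (+%d days): %d active redirects remain",
                cfg$survival_median_days,
                sum(later$category == "active_redirect")))
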
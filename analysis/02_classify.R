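#!/usr/bin/env Rscript
# Validate the audit and tabulate link categories, overall and per country —
# the n (%) summary that frames how much of each SERP is poisoned.

suppressPackageStartupMessages(library(serpnet))

audit <- read_audit("results/synthetic_audit.csv", rank_max = 40)
stopifnot(nrow(audit_errors(audit)) == 0)
message(sprintf("validated %d records, %d rejected", nrow(audit),
                nrow(audit_errors(audit))))

overall <- tabulate_categories(audit)
readr::write_csv(render_breakdown(overall), "results/categories_overall.csv")
write_breakdown_json(overall, "results/categories_overall.json")
print(render_breakdown(overall)[, c("category", "n_pct")], n = 7)

by_country <- tabulate_categories(audit, group_by = "country")
readr::write_csv(by_country, "results/categories_by_country.csv")
message(sprintf("per-country breakdown: %d rows over %d countries",
                nrow(by_country), length(unique(by_country$country))))

act_share <- overall$share[overall$category == "active_redirect"]
message(sprintf("active redirects are %s%% of evaluated results", act_share))
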
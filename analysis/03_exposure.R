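#!/usr/bin/env Rscript
# Prevalence and cumulative-CTR exposure per country and per active
# ingredient. The CTR model uses the placeholder head table (the exponential
# evaluated at ranks 1-10) plus the exponential tail for ranks 11-40;
# substitute a measured head table for substantive exposure estimates.

suppressPackageStartupMessages(library(serpnet))

audit <- read_audit("results/synthetic_audit.csv", rank_max = 40)
model <- rank_ctr_model()
print(model)

by_country <- exposure_report(audit, model, group_by = "country")
readr::write_csv(by_country, "results/exposure_by_country.csv")
top <- by_country[order(-by_country$prevalence), ][1:3, ]
message("highest prevalence: ",
        paste(sprintf("%s %.1f%%", top$country, top$prevalence), collapse = ", "))

by_both <- exposure_report(audit, model, group_by = c("country", "api"))
readr::write_csv(by_both, "results/exposure_by_country_api.csv")
hi <- by_both[which.max(by_both$cumulative_ctr), ]
message(sprintf("largest cumulative CTR: %s/%s at %.1f%% (prevalence %.1f%%)",
                hi$country, hi$api, hi$cumulative_ctr, hi$prevalence))
message("prevalence and cumulative CTR are complementary: many low-ranked ",
        "compromised links give high prevalence but little click exposure")
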
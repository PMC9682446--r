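# serpnet

Surveillance analysis of **search-engine poisoning** ("search-redirection
attacks") that funnels search users to illegal online pharmacies.

Illegal medicine vendors operate as affiliate networks: attackers hack
legitimate but vulnerable websites, inject keyword-stuffed content so the
hacked pages rank high in organic search results, and silently redirect
visitors who click those results to a small set of destination pharmacy
domains. Auditing search-engine results pages (SERPs) for such links is a
public-health surveillance task: the audits are compiled by hand (cloaking
defeats automated crawling), and the analysis must quantify both how common
the poisoned links are and how likely users are to click them.

`serpnet` implements that analysis pipeline for anyone studying illicit
online pharmacy promotion — pharmacovigilance researchers, infodemiologists,
and regulators:

* **Audit records** — a validated CSV schema for documented search results
  (country, language, active ingredient, rank, link category, redirection
  destination, infection life-cycle state), with row-addressed error
  reporting, registrable-domain extraction (public-suffix aware), life-cycle
  classification (future → active → inactive), and n (%) category tables.
* **Exposure metrics** — the two headline statistics:
  * *prevalence*: compromised links / evaluated links, as a percentage;
  * *cumulative click-through rate*: `sum over compromised positions r of
    CTR(r)`, where `CTR(r)` is a per-rank click probability — an empirical
    head table for ranks 1–10 and the exponential tail
    `CTR(r) = a·e^(−b·r)` (defaults `a = 26.76`, `b = 0.258`) for ranks
    11–40 — plus the log-linear trend-line fitter that recovers `(a, b, R²)`
    from per-rank data.
* **Redirection network** — the weighted directed graph from compromised
  source domains to destination pharmacies (edge weight = link count, edge
  label = ingredient set), per-node in-degree / distinct sources / PageRank
  (power iteration, uniform teleport, dangling mass redistributed), hub
  concentration and long-tail summaries, legitimacy/traffic joins, and
  GraphML / GEXF / CSV export for Gephi.
* **Synthetic generator** — a seeded simulator of whole audits with the
  affiliate-network structure the field reports (hub-dominated Zipf
  attachment, calibrated single-destination fraction, fan-out and
  multi-ingredient rates, geometric infection survival), so every stage is
  testable without live scraping (automated search queries are prohibited by
  providers, and no real audit is bundled).

## Worked example

The `analysis/` scripts run the whole study on a simulated audit
(`Rscript analysis/01_simulate.R` … `05_report.R`). Condensed:

```r
library(serpnet)

cfg   <- synthetic_config(seed = 20201115)   # 12 countries x 4 drugs x top-40
audit <- generate_audit(cfg)                 # 1920 documented results

exposure_report(audit, rank_ctr_model(), group_by = "country")
source_summary(audit)
network_stats(build_network(audit), k = 3)
```

which prints (seed `20201115`):

```
simulated 1920 search results across 12 countries
compromised: 380 (19.8%), active redirects: 342
highest prevalence: HU 23.1%, IT 22.5%, FI 21.9%
largest cumulative CTR: FI/sildenafil at 64.1% (prevalence 35.0%)
network: 267 nodes, 303 edges, 65 destinations, average degree 1.135
top-3 destinations receive 36.8% of all 342 incoming links; 46% of destinations get only 1-2
sources: 202; single-destination 69.8%, multi-ingredient 27.7%, mean fan-out 1.50
```

Reading: 380 of the 1920 evaluated links (19.8%) were compromised; the
redirection graph is hub-dominated (three destinations soak up over a third
of incoming links while most get one or two); and the largest exposure index
(64.1%) flags the country×drug panel whose compromised links sit at
high-CTR ranks. Prevalence and cumulative CTR are complementary: many
low-ranked poisoned links raise prevalence but add little click exposure.

The default head CTR table is a documented placeholder (the exponential
evaluated at ranks 1–10); pass measured per-rank CTRs to `rank_ctr_model()`
for substantive exposure estimates.

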
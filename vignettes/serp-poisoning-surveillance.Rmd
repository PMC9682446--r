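---
title: "Methods: surveillance of SERP poisoning by illegal pharmacy networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance of SERP poisoning by illegal pharmacy networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpnet)
```

## The surveillance problem

Illegal online pharmacies recruit customers through *search-redirection
attacks*: a legitimate website is hacked, injected with keyword-stuffed
content so it ranks high in organic search results for medicine-purchase
queries (for instance "buy sildenafil" in the language of each country), and
then silently redirects visitors to a destination pharmacy domain. Because
the hacked site cloaks — showing crawlers the keyword page and humans the
redirect — detection is manual: auditors document what each ranked search
result actually is. This package analyses such audits.

A documented search result carries: audit date, country and search language,
active ingredient searched (the four PDE5 inhibitors sildenafil, tadalafil,
vardenafil and avanafil), search phrase, result URL and its registrable
source domain, 1-based rank among organic results, one of seven link
categories, and — for redirects — the destination URL/domain and a
life-cycle state. Rank ceilings are a property of the dataset (top-20 for
longitudinal national audits, top-40 for a one-off international audit), so
`read_audit()` takes `rank_max` as configuration rather than hard-coding
either.

### Link categories and the infection life cycle

Seven mutually exclusive categories cover what a ranked result can be:
legitimate pharmacy, national (domestic) illegal seller, active redirect to
an international vendor, compromised site without redirection, inaccessible
page (404), dietary-supplement shop, and other non-seller. The three
"compromised" categories map onto an infection life cycle:

* **future** — injected content present, no automatic redirection yet;
* **active** — redirection to a destination observed;
* **inactive** — formerly redirecting, now broken or unreachable.

`classify_lifecycle()` is total on non-contradictory flag observations. A
link reported both redirecting and inaccessible is rejected as a
contradictory observation. One genuinely open case is a compromised link
with no injected content, no redirection, and no active history: we return
`future` (the flag set most consistent with an infection that has not
surfaced yet), since the link reached the classifier only because it was
flagged compromised upstream. The schema also carries an optional `excluded`
flag for results the auditor deems non-relevant; its semantics are the
auditor's, and every summarizer drops excluded rows.

### Domain identity

All aggregation keys on the *registrable domain*, lower-cased and
public-suffix aware (`blog.example.co.uk` → `example.co.uk`). Hacked pages
live on subpaths and subdomains of one compromised site, so anything finer
would fragment a single infection into several. The suffix table is an
embedded snapshot of common multi-label rules; unknown final labels are
treated as single-label suffixes. That snapshot is deliberately small — an
audit pipeline needs stability, not the full (and changing) public-suffix
list; domains whose registrable cut the snapshot misses aggregate one label
short, which is harmless for within-audit consistency.

## Exposure metrics

Two complementary statistics measure consumer exposure per group (usually
country × ingredient):

**Prevalence** is the share of evaluated links that are compromised,
`100 · k / n`. By default "compromised" includes all three life-cycle
categories; a stricter active-redirects-only definition is a flag.

**Cumulative CTR** sums a per-rank click probability over the rank positions
of the group's compromised links. The per-rank model is piecewise:

* ranks 1–10: an empirical head table of CTR percentages (industry click
  studies measure these; they are inputs, not derivable);
* ranks 11–40: the exponential tail `CTR(r) = a·e^(−b·r)` with defaults
  `a = 26.76` (percent) and `b = 0.258` (per rank), the trend line fitted
  through first-page click data.

The head table for ranks 1–10 is not published with the audit methodology,
so the package ships a clearly-labelled placeholder (the same exponential
evaluated at ranks 1–10). Consequently cumulative-CTR *values* computed with
defaults are demonstrations; exposure comparisons across groups are still
meaningful because the model is shared. Published per-country cumulative-CTR
figures cannot be reproduced without the original head table and per-record
ranks; the suite instead verifies the tail equation pointwise, the
trend-line fitter's exact recovery of `(a, b)` on noiseless data (R² is
computed on the log scale, as spreadsheet trend lines do), and the additivity
and monotonicity of the cumulative sum. Two further choices: no continuity
is forced at the rank-10/11 boundary (the construction does not guarantee
it; the model prints both boundary values), and cumulative CTR is treated as
an exposure *index*, not a probability — sums above 100% are flagged
conceptually but never capped.

Reported percentages round half-up (2.5 → 3), matching the convention of
printed n (%) tables; half-even rounding would disagree with published
tables at exact halves. Table shares default to integers, prevalences to one
decimal; both are configurable.

## The redirection network

Active redirects define a weighted directed graph: source domain →
destination domain, edge weight = number of documented links for the pair,
edge label = the set of ingredients searched. Metrics:

* **in-degree** of a destination counts *links* (edge-weight sum), not
  distinct edges — a destination with 16 referring links has in-degree 16.
  `distinct_sources` is reported separately to disambiguate.
* **PageRank** by power iteration on the weighted graph: transition
  probabilities proportional to edge weights, uniform teleport with damping
  0.85, dangling mass redistributed uniformly, L1 convergence at 1e-9,
  iteration cap 1000 (all config-exposed; graph tools do not agree on
  defaults, these match common practice). The implementation is checked
  against a dense linear-solve oracle and an independent library
  implementation on random digraphs up to 50 nodes.
* **average degree** = distinct edges / all nodes (isolates included) —
  the only convention under which a sparse thinning graph can fall below 1.
* **hub concentration**: share of incoming links held by the top-k
  destinations (k = 3 default) and the share of destinations with in-degree
  1–2 (the long tail). Destination-only node universes are used for both;
  sources appear in neither numerator.

Destination metadata joins attach a legitimacy rating (approved /
unlicensed / rogue / not in database) and monthly unique visitors;
`aggregate_visitors()` sums visitors over (optionally pharmacy-named)
destinations and reports coverage gaps rather than imputing. Pharmacy-name
detection matches a configurable term list (`rx`, `pharm`, `med(s)`,
`pill(s)`, `drug`) against the domain label with the public suffix stripped,
so a term hiding in a TLD never matches. Graphs export to GraphML, GEXF and
edge/node CSV with all attributes, and re-import losslessly.

## The synthetic audit generator

No real audit data can be bundled (none is deposited, and automated search
querying is prohibited by providers), so the generator is a first-class
module that emulates the study conditions:

* 12 countries × 4 ingredients × top-40 ranks = 1920 evaluated results;
* each result independently compromised with probability 0.198; compromised
  results are active redirects with probability 0.90, no-redirect 0.016,
  inaccessible 0.084; benign results follow the published national category
  proportions (no legitimate pharmacies, consistent with markets where
  prescription medicines may not be sold online);
* destination attachment is Zipf over 73 candidate domains with exponent 1 —
  the minimal one-parameter heavy-tail family that reproduces hub dominance
  (analytically, the top-3 share under exponent 1 over 73 domains is
  ~0.377, above the observed one-third threshold);
* per-source fan-out is 1 with probability 0.696, else 1 + zero-truncated
  Poisson with its rate solved so the mean is 1.49 — one free parameter
  matching both the single-destination mass and the mean;
* each source emits one link per distinct destination plus
  Poisson(0.16) repeat links, putting links-per-source near the observed
  380/230; the multi-ingredient flag (marginal 0.283) is rescaled onto
  sources with ≥ 2 links, the only ones that can realise it;
* infection survival is geometric with median 19 days; an optional
  two-component mixture adds a persistent subpopulation (weight 0.354,
  median 170 days) calibrated so ~17% of infections survive 6 months and
  ~8% a year while the overall median stays 19 days — quantiles reported in
  prior measurement studies; the single-geometric default is used wherever
  the heavy tail is not the object of study;
* destination profiles: 79% rogue, log-uniform visitors over 300–600,000
  (spanning observed per-domain counts), 45% missing traffic data, 87.5% of
  destinations pharmacy-named.

Country × ingredient infection rates are independent by assumption; their
joint distribution is unreported. A single integer seed drives every stream
through a named-stream discipline (each stage hashes `(seed, stream-name)`),
so stages regenerate independently and identical configs are bit-identical
across runs.

Because active links must partition a finite per-country slot pool, source
assembly has edge effects; leftover slots that cannot realise a freshly
drawn source plan are attached as repeat links to existing compatible
sources, which leaves the calibrated per-source statistics unchanged. The
residual bias is an order of magnitude below sampling error at the default
size (checked by the parameter-recovery tests, which push generated audits
through the real analysis stages and require the configured prevalence,
single-destination fraction, multi-ingredient fraction, fan-out mean and
survival median back within exact-binomial/bootstrap 99% intervals).

What passing these tests does **not** show about real data: real infections
are not independent across ranks (one hacked site often occupies several
positions), real rank distributions of compromised links are not uniform,
and real destination popularity need not be Zipf. The generator's purpose is
pipeline correctness and calibrated structure, not forecasting.

## Numerical and degenerate-input choices

* Empty groups tabulate with zero counts, shares reported 0 with an
  `empty` flag rather than NaN.
* Zero-prevalence audits, empty networks and all-missing visitor tables all
  produce complete, flagged outputs instead of errors; genuinely
  contradictory inputs (active redirect without destination, negative
  visitor counts, rank 0) fail loudly with row-addressed messages.
* PageRank on a single isolated node returns 1 (normalization); two-node
  symmetric cycles return 0.5/0.5 (exactness checks).
* The trend-line fitter requires ≥ 3 positive points; R² is computed from
  residuals directly to avoid degenerate summaries on perfect fits.
* All randomness is confined to the generator; every analysis stage is
  deterministic, and the report manifest hashes all output-affecting
  parameters so reruns are verifiable.

## Problem sizes

The test suite and the acceptance script run the generator at the study's
own scale (1920-record audits, ~200 source infections, networks of a few
hundred nodes) and the PageRank oracle comparisons at up to 50 nodes —
desk-scale sizes chosen because every published summary they check was
itself computed on data of this size; everything completes in seconds.

## Known limitations

* Cumulative CTR with the placeholder head table is comparative, not
  absolute.
* The public-suffix snapshot is partial by design.
* The generator's affiliate structure is calibrated marginally; joint
  structure (country × ingredient × destination correlations) is modelled
  as independent.
* Life-cycle observation flags are inputs: the package classifies, it does
  not probe websites.
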
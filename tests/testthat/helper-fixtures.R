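# Fixture builders shared across the suite. All fixtures are constructed in
# code; none are stored on disk.

# A minimal valid audit row; override any field.
audit_row <- function(..., rank = 1L, category = "other_non_seller",
                      country = "HU", api = "sildenafil",
                      source = "example-site.hu", destination = NA_character_,
                      lifecycle = NA_character_, date = as.Date("2019-08-15")) {
  tibble::tibble(
    audit_date = date, country = country, language = "hu", api = api,
    search_phrase = paste("vasarlas", api),
    result_url = paste0("http://", source, "/p"), source_domain = source,
    rank = as.integer(rank), category = category,
    destination_url = ifelse(is.na(destination), NA_character_,
                             paste0("https://", destination, "/")),
    destination_domain = destination, lifecycle = lifecycle, excluded = FALSE,
    ...
  )
}

# An audit with the given per-category counts; compromised categories get a
# lifecycle and active redirects a destination. Ranks cycle 1..rank_max.
audit_with_counts <- function(counts, rank_max = 20L, country = "HU",
                              api = "sildenafil", destination = "acs-pharmacy.com",
                              date = as.Date("2019-08-15")) {
  rows <- list()
  i <- 0L
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0) next
    lc <- c(active_redirect = "active", compromised_no_redirect = "future",
            not_accessible = "inactive")[cat]
    dest <- if (cat == "active_redirect") destination else NA_character_
    for (j in seq_len(k)) {
      i <- i + 1L
      rows[[i]] <- audit_row(rank = ((i - 1L) %% rank_max) + 1L, category = cat,
                             country = country, api = api,
                             source = sprintf("hacked-%03d.hu", i),
                             destination = dest,
                             lifecycle = if (is.na(lc)) NA_character_ else lc,
                             date = date)
    }
  }
  serpnet::validate_audit(dplyr::bind_rows(rows), rank_max = rank_max)
}

# The national August-2019 snapshot shape: 80 top-20 results with category
# counts 0/8/43/5/2/9/13.
national_aug2019_audit <- function() {
  audit_with_counts(c(legitimate_pharmacy = 0, national_illegal_seller = 8,
                      active_redirect = 43, compromised_no_redirect = 5,
                      not_accessible = 2, dietary_supplement_shop = 9,
                      other_non_seller = 13), rank_max = 20L)
}

# A country panel of n_total top-40 results with n_compromised active
# redirects at the given ranks.
country_panel <- function(country, n_compromised, n_total = 160L,
                          comp_ranks = ((seq_len(n_compromised) - 1L) %% 40L) + 1L) {
  stopifnot(length(comp_ranks) == n_compromised)
  rows <- lapply(seq_len(n_total), function(i) {
    comp <- i <= n_compromised
    audit_row(
      rank = if (comp) comp_ranks[i] else ((i - 1L) %% 40L) + 1L,
      category = if (comp) "active_redirect" else "other_non_seller",
      country = country, api = serpnet::audit_apis()[((i - 1L) %% 4L) + 1L],
      source = sprintf("panel-%s-%03d.com", tolower(country), i),
      destination = if (comp) "ezshopremedieshere.com" else NA_character_,
      lifecycle = if (comp) "active" else NA_character_,
      date = as.Date("2020-11-15")
    )
  })
  serpnet::validate_audit(dplyr::bind_rows(rows), rank_max = 40L)
}

# Random weighted digraph on n nodes as an igraph, for PageRank oracles.
random_digraph <- function(n, p_edge = 0.2, max_w = 5L) {
  adj <- matrix(stats::rbinom(n * n, 1, p_edge) *
                  sample.int(max_w, n * n, replace = TRUE), n, n)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed", weighted = TRUE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::V(g)$role <- "both"
  g
}

# Closed-form PageRank oracle: solve the damped linear system on the dense
# row-stochastic transition matrix (dangling rows uniform).
pagerank_dense_oracle <- function(g, damping = 0.85) {
  n <- igraph::vcount(g)
  W <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  for (i in seq_len(nrow(el))) W[el[i, 1], el[i, 2]] <- W[el[i, 1], el[i, 2]] + w[i]
  rs <- rowSums(W)
  P <- matrix(1 / n, n, n)
  ok <- rs > 0
  P[ok, ] <- W[ok, , drop = FALSE] / rs[ok]
  solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
}

# Exact binomial 99% acceptance band around probability p at size n.
binom_band99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
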
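test_that("network construction aggregates links into weighted edges", {
  recs <- dplyr::bind_rows(
    audit_row(rank = 1, category = "active_redirect", source = "hacked-a.hu",
              destination = "acs-pharmacy.com", lifecycle = "active"),
    audit_row(rank = 2, category = "active_redirect", source = "hacked-a.hu",
              destination = "acs-pharmacy.com", lifecycle = "active",
              api = "tadalafil"),
    audit_row(rank = 3, category = "other_non_seller", source = "blog.hu")
  )
  net <- build_network(validate_audit(recs, rank_max = 20))
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$weight, 2)
  expect_equal(igraph::E(net)$apis, "sildenafil,tadalafil")
  expect_setequal(igraph::V(net)$name, c("hacked-a.hu", "acs-pharmacy.com"))
})

test_that("empty and malformed inputs are handled", {
  empty <- build_network(audit_row(category = "other_non_seller"))
  expect_equal(igraph::vcount(empty), 0L)
  bad <- audit_row(category = "active_redirect", lifecycle = "active")
  expect_error(build_network(bad), "data error")
})

test_that("a hub destination accumulates in-degree equal to its link count", {
  rows <- lapply(1:16, function(i) {
    audit_row(rank = (i - 1) %% 20 + 1, category = "active_redirect",
              source = sprintf("hacked-%02d.hu", i),
              destination = "acs-pharmacy.com", lifecycle = "active")
  })
  net <- build_network(validate_audit(dplyr::bind_rows(rows), rank_max = 20))
  m <- node_metrics(net)
  hub <- m[m$domain == "acs-pharmacy.com", ]
  expect_equal(hub$in_degree, 16)
  expect_equal(hub$distinct_sources, 16L)
  expect_true(all(m$in_degree >= m$distinct_sources))
})

test_that("PageRank handles symmetric and degenerate graphs", {
  cyc <- igraph::make_graph(c("A", "B", "B", "A"), directed = TRUE)
  igraph::E(cyc)$weight <- c(1, 1)
  igraph::V(cyc)$role <- "both"
  m <- node_metrics(cyc)
  expect_equal(m$pagerank, c(0.5, 0.5), tolerance = 1e-9)
  lone <- igraph::make_empty_graph(1, directed = TRUE)
  igraph::V(lone)$name <- "only.com"
  igraph::V(lone)$role <- "destination"
  expect_equal(node_metrics(lone)$pagerank, 1, tolerance = 1e-12)
  expect_error(node_metrics(cyc, damping = 1.2), "damping")
})

test_that("power-iteration PageRank matches independent oracles on random digraphs", {
  set.seed(2024)
  for (n in c(3, 8, 20, 50)) {
    g <- random_digraph(n)
    m <- node_metrics(g)
    pr <- m$pagerank[match(igraph::V(g)$name, m$domain)]
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    oracle <- pagerank_dense_oracle(g)
    expect_equal(pr, oracle, tolerance = 1e-8)
    # cross-check against the independent igraph implementation
    ig <- igraph::page_rank(g, damping = 0.85, weights = igraph::E(g)$weight)$vector
    expect_equal(pr, unname(ig), tolerance = 1e-6)
  }
})

test_that("network statistics summarise size, concentration, and the long tail", {
  # 6 nodes, 4 edges: two 2-source stars onto two destinations
  rows <- dplyr::bind_rows(
    lapply(1:2, function(i) audit_row(rank = i, category = "active_redirect",
                                      source = sprintf("s%d.hu", i),
                                      destination = "evo-pharmacy.com",
                                      lifecycle = "active")),
    lapply(3:4, function(i) audit_row(rank = i, category = "active_redirect",
                                      source = sprintf("s%d.hu", i),
                                      destination = "eu-pharm.de",
                                      lifecycle = "active"))
  )
  net <- build_network(validate_audit(rows, rank_max = 20))
  st <- network_stats(net)
  expect_equal(st$n_nodes, 6L)
  expect_equal(st$n_edges, 4L)
  expect_equal(round(st$average_degree, 3), 0.667)
  # star: all links into one destination
  star_rows <- lapply(1:5, function(i) {
    audit_row(rank = i, category = "active_redirect", source = sprintf("h%d.hu", i),
              destination = "hub-pharm.com", lifecycle = "active")
  })
  star <- build_network(validate_audit(dplyr::bind_rows(star_rows), rank_max = 20))
  expect_equal(network_stats(star, k = 3)$top_k_share, 1)
  expect_error(network_stats(star, k = 0), "k must be")
  st0 <- network_stats(build_network(audit_row(category = "other_non_seller")))
  expect_true(st0$empty)
  expect_equal(st0$average_degree, 0)
})

test_that("a long-tailed destination set yields the expected low-degree share", {
  # 73 destinations: 41 with in-degree 1 or 2, 32 with in-degree 3
  k <- 0L
  rows <- list()
  add_links <- function(dest, n_links) {
    for (j in seq_len(n_links)) {
      k <<- k + 1L
      rows[[k]] <<- audit_row(rank = (k - 1) %% 40 + 1, category = "active_redirect",
                              source = sprintf("src-%03d.com", k),
                              destination = dest, lifecycle = "active")
    }
  }
  for (i in 1:30) add_links(sprintf("tail-one-%02d.com", i), 1L)
  for (i in 1:11) add_links(sprintf("tail-two-%02d.com", i), 2L)
  for (i in 1:32) add_links(sprintf("mid-%02d.com", i), 3L)
  net <- build_network(validate_audit(dplyr::bind_rows(rows), rank_max = 40))
  st <- network_stats(net)
  expect_equal(st$n_destinations, 73L)
  expect_equal(round(100 * st$low_degree_share), 56)
})

test_that("uniform in-degree-1 networks have degenerate concentration", {
  rows <- lapply(1:10, function(i) {
    audit_row(rank = i, category = "active_redirect", source = sprintf("u%d.hu", i),
              destination = sprintf("dest-%02d.com", i), lifecycle = "active")
  })
  net <- build_network(validate_audit(dplyr::bind_rows(rows), rank_max = 20))
  st <- network_stats(net, k = 3)
  expect_equal(st$low_degree_share, 1)
  expect_equal(st$top_k_share, 3 / 10)
})

test_that("pharmacy-name detection matches terms in the domain label only", {
  expect_true(pharmacy_named("rx-24-online.com"))
  expect_false(pharmacy_named("forecastarrays.us"))
  expect_true(pharmacy_named("evo-pharmacy.com"))
  expect_true(pharmacy_named("your-meds-store.com"))
  # term hiding in the suffix must not match
  expect_false(pharmacy_named("garden-blog.rx", terms = "rx"))
  expect_equal(pharmacy_named(c("pills-group.com", "sunnyfields.net")),
               c(TRUE, FALSE))
})

test_that("visitor aggregation sums covered destinations and reports gaps", {
  profiles <- tibble::tibble(
    domain = c("acs-pharmacy.com", "1-pharm.com", "specialmedassortment.com",
               "myworldpharma.com", "pharmpillsonline.com", "nodata-pharm.com"),
    legitimacy = c("rogue", "rogue", "rogue", "not_in_database", "rogue", "rogue"),
    monthly_unique_visitors = c(155400, 11000, 3600, 4000, 800, NA)
  )
  agg <- aggregate_visitors(profiles)
  expect_equal(agg$total, 174800)
  expect_equal(agg$n_included, 5L)
  expect_equal(agg$missing_visitors, "nodata-pharm.com")
  # all-missing: zero with a warning
  none <- tibble::tibble(domain = "x-pharm.com", legitimacy = "rogue",
                         monthly_unique_visitors = NA_real_)
  expect_warning(agg0 <- aggregate_visitors(none), "no destination profile")
  expect_equal(agg0$total, 0)
  # the pharmacy-name filter excludes non-flagged domains
  mixed <- tibble::tibble(domain = c("rx-shop.com", "forecastarrays.us"),
                          monthly_unique_visitors = c(100, 1000))
  agg2 <- aggregate_visitors(mixed, require_pharmacy_named = TRUE)
  expect_equal(agg2$total, 100)
  expect_equal(agg2$excluded_by_name, "forecastarrays.us")
  bad <- tibble::tibble(domain = "a-pharm.com", monthly_unique_visitors = -5)
  expect_error(aggregate_visitors(bad), "negative visitor")
})

test_that("graph export round-trips across all formats", {
  cfg <- synthetic_config(seed = 5)
  audit <- generate_audit(cfg)
  net <- build_network(audit)
  metrics <- node_metrics(net)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    o <- order(el[, 1], el[, 2])
    list(nodes = sort(igraph::V(g)$name),
         edges = cbind(el, igraph::E(g)$weight, igraph::E(g)$apis)[o, , drop = FALSE])
  }
  for (fmt in c("graphml", "gexf", "edge_csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(net, f, fmt, metrics = metrics)
    back <- import_graph(f, fmt)
    expect_equal(canon(back), canon(net), info = fmt)
  }
  # empty network: a valid, re-importable document
  f <- withr::local_tempfile(fileext = ".graphml")
  empty <- build_network(audit_row(category = "other_non_seller"))
  export_graph(empty, f, "graphml")
  expect_equal(igraph::vcount(import_graph(f, "graphml")), 0L)
  # edge-CSV row count equals distinct source-destination pairs
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_graph(net, f2, "edge_csv")
  expect_equal(nrow(readr::read_csv(f2, show_col_types = FALSE)),
               igraph::ecount(net))
})
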
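#' Build the redirection network from active-redirect records
#'
#' Constructs the weighted directed graph whose nodes are registrable
#' domains and whose edges run from a compromised source domain to the
#' destination pharmacy domain its visitors are redirected to. Multiple
#' audited links with the same (source, destination) pair increase the weight
#' of the edge; the set of active ingredients searched for is kept as an edge
#' attribute.
#'
#' @param records Validated audit tibble; rows with category other than
#'   `active_redirect` are ignored. An active redirect lacking a destination
#'   is a data error (those rows are listed in the message).
#' @return An `igraph` directed graph. Vertex attributes: `name` (domain),
#'   `role` (source / destination / both). Edge attributes: `weight` (link
#'   count), `apis` (comma-joined ingredient labels).
#' @export
build_network <- function(records) {
  act <- records[records$category == "active_redirect", , drop = FALSE]
  bad <- which(is.na(act$destination_domain))
  if (length(bad) > 0) {
    stop("data error: active redirect(s) without destination at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(act) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    return(g)
  }
  edges <- dplyr::summarise(
    dplyr::group_by(act, source = .data$source_domain,
                    destination = .data$destination_domain),
    weight = dplyr::n(),
    apis = paste(sort(unique(.data$api)), collapse = ","),
    .groups = "drop"
  )
  nodes <- tibble::tibble(name = union(edges$source, edges$destination))
  nodes$role <- dplyr::case_when(
    nodes$name %in% edges$source & nodes$name %in% edges$destination ~ "both",
    nodes$name %in% edges$source ~ "source",
    TRUE ~ "destination"
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

# Weighted PageRank by power iteration: uniform teleport, dangling mass
# redistributed uniformly, convergence in L1.
pagerank_power <- function(g, damping = 0.85, tol = 1e-9, max_iter = 1000L) {
  n <- igraph::vcount(g)
  if (n == 0) return(structure(numeric(0), iterations = 0L, converged = TRUE))
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  out_strength <- rep(0, n)
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) out_strength[el[i, 1]] <- out_strength[el[i, 1]] + w[i]
  }
  r <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new <- rep((1 - damping) / n, n)
    dangling <- sum(r[out_strength == 0])
    new <- new + damping * dangling / n
    if (nrow(el) > 0) {
      contrib <- damping * r[el[, 1]] * w / out_strength[el[, 1]]
      for (i in seq_len(nrow(el))) new[el[i, 2]] <- new[el[i, 2]] + contrib[i]
    }
    delta <- sum(abs(new - r))
    r <- new
    if (delta < tol || iter >= max_iter) break
  }
  structure(r, iterations = iter, converged = delta < tol)
}

#' Per-node metrics of a redirection network
#'
#' Computes, for every domain in the network, the in-degree as the total
#' incoming link count (sum of incoming edge weights — a destination hit by
#' 16 individual referring links has in-degree 16 even if they share source
#' domains), the number of distinct referring source domains, and the
#' PageRank importance score. PageRank is computed by power iteration on the
#' weighted directed graph with uniform teleport and uniform redistribution
#' of dangling mass, so scores sum to 1.
#'
#' @param net Graph from [build_network()].
#' @param damping Teleport damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter Iteration cap; default 1000.
#' @return Tibble: domain, role, in_degree, distinct_sources, pagerank.
#'   Attributes `pagerank_iterations` and `pagerank_converged` report the
#'   power iteration outcome.
#' @export
node_metrics <- function(net, damping = 0.85, tol = 1e-9, max_iter = 1000L) {
  if (damping <= 0 || damping >= 1) {
    stop("configuration error: damping must lie strictly in (0, 1)")
  }
  if (igraph::vcount(net) == 0) stop("node_metrics requires a non-empty network")
  pr <- pagerank_power(net, damping = damping, tol = tol, max_iter = max_iter)
  out <- tibble::tibble(
    domain = igraph::V(net)$name,
    role = igraph::V(net)$role,
    in_degree = unname(igraph::strength(net, mode = "in",
                                        weights = igraph::E(net)$weight)),
    distinct_sources = unname(igraph::degree(net, mode = "in")),
    pagerank = as.numeric(pr)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$in_degree), .data$domain)
  attr(out, "pagerank_iterations") <- attr(pr, "iterations")
  attr(out, "pagerank_converged") <- attr(pr, "converged")
  out
}

#' Whole-network summary statistics
#'
#' Average degree (distinct edges per node, counted over all nodes including
#' isolates), hub concentration (share of all incoming links received by the
#' k destinations with the highest in-degree), and the long tail (share of
#' destinations receiving only one or two incoming links). In-degree counts
#' links, i.e. sums edge weights.
#'
#' @param net Graph from [build_network()].
#' @param k Number of top destinations for the concentration share; >= 1.
#' @return Tibble row: n_nodes, n_edges, n_destinations, total_links,
#'   average_degree, top_k_share, low_degree_share, empty.
#' @export
network_stats <- function(net, k = 3L) {
  if (k < 1) stop("configuration error: k must be >= 1")
  n_nodes <- igraph::vcount(net)
  n_edges <- igraph::ecount(net)
  if (n_nodes == 0) {
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, n_destinations = 0L,
                          total_links = 0, average_degree = 0,
                          top_k_share = 0, low_degree_share = 0, empty = TRUE))
  }
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, n_edges)
  role <- igraph::V(net)$role
  is_dest <- role %in% c("destination", "both")
  indeg <- igraph::strength(net, mode = "in", weights = w)[is_dest]
  total_links <- sum(w)
  top_k <- sum(sort(indeg, decreasing = TRUE)[seq_len(min(k, length(indeg)))])
  tibble::tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    n_destinations = sum(is_dest),
    total_links = total_links,
    average_degree = n_edges / n_nodes,
    top_k_share = if (total_links > 0) top_k / total_links else 0,
    low_degree_share = if (length(indeg) > 0) mean(indeg %in% c(1, 2)) else 0,
    empty = FALSE
  )
}

#' Does a domain carry a pharmacy-flavoured name?
#'
#' Case-insensitive substring match of configured pharmacy terms against the
#' label portion of the registrable domain (the public suffix is excluded, so
#' a term hiding in the TLD never matches).
#'
#' @param domain Character vector of registrable domains.
#' @param terms Terms to match; the default list covers the common
#'   pharmacy-name fragments (rx, pharm, med, pill, drug ...).
#' @return Logical vector.
#' @export
pharmacy_named <- function(domain,
                           terms = c("rx", "pharm", "med", "meds", "pill",
                                     "pills", "drug")) {
  stopifnot(all(nzchar(domain)))
  label <- domain_label(domain)
  vapply(label, function(x) {
    any(vapply(terms, function(t) grepl(t, x, ignore.case = TRUE, fixed = FALSE),
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Total monthly unique visitors over destination profiles
#'
#' Sums estimated monthly unique visitors over destination-domain profiles,
#' optionally restricted to pharmacy-named domains, and reports which domains
#' were excluded for lacking visitor data (traffic databases do not cover
#' every domain).
#'
#' @param profiles Tibble with columns `domain`, `monthly_unique_visitors`
#'   (NA when unknown) and, if `require_pharmacy_named`, a logical
#'   `pharmacy_named` column (computed from the domain if absent).
#' @param require_pharmacy_named Restrict the sum to pharmacy-named domains.
#' @return List: `total` (visitor sum), `n_included`, `included` (tibble of
#'   summed profiles), `missing_visitors` (domains excluded for lacking
#'   data), `excluded_by_name` (domains excluded by the name filter).
#' @export
aggregate_visitors <- function(profiles, require_pharmacy_named = FALSE) {
  v <- profiles$monthly_unique_visitors
  if (any(!is.na(v) & v < 0)) stop("data error: negative visitor count")
  if (require_pharmacy_named && !("pharmacy_named" %in% names(profiles))) {
    profiles$pharmacy_named <- pharmacy_named(profiles$domain)
  }
  name_ok <- if (require_pharmacy_named) profiles$pharmacy_named else rep(TRUE, nrow(profiles))
  sel <- name_ok & !is.na(v)
  res <- list(
    total = sum(v[sel]),
    n_included = sum(sel),
    included = profiles[sel, , drop = FALSE],
    missing_visitors = profiles$domain[name_ok & is.na(v)],
    excluded_by_name = profiles$domain[!name_ok]
  )
  if (res$n_included == 0) {
    warning("no destination profile carried visitor data; total is 0")
  }
  res
}
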
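#' Link categories of an audited search result
#'
#' The seven mutually exclusive categories a documented organic search result
#' can fall into during a pharmacy-poisoning SERP audit: a legitimate online
#' pharmacy, a national (domestic) illegal seller, a compromised site actively
#' redirecting to an international illegal vendor, a compromised site without
#' redirection (injected content only), a result not accessible at evaluation
#' time (e.g. 404), a dietary-supplement web shop, and any other site not
#' offering products for sale.
#'
#' @return Character vector of the seven category labels, in reporting order.
#' @export
link_categories <- function() {
  c("legitimate_pharmacy", "national_illegal_seller", "active_redirect",
    "compromised_no_redirect", "not_accessible", "dietary_supplement_shop",
    "other_non_seller")
}

#' Categories counted as compromised
#'
#' By default a result is "compromised" (infected) if it is an active
#' redirect, a hacked page without redirection, or a formerly hacked page now
#' inaccessible. Prevalence and CTR exposure are computed over this set;
#' pass `active_only = TRUE` to restrict to active redirects.
#'
#' @param active_only Count only active redirects as compromised.
#' @return Character vector of category labels.
#' @export
compromised_categories <- function(active_only = FALSE) {
  if (active_only) "active_redirect"
  else c("active_redirect", "compromised_no_redirect", "not_accessible")
}

lifecycle_states <- function() c("future", "active", "inactive")

# Columns of the audit schema, in canonical order. source_domain and
# destination_domain are derived from the URLs when absent.
audit_columns <- function() {
  c("audit_date", "country", "language", "api", "search_phrase",
    "result_url", "source_domain", "rank", "category",
    "destination_url", "destination_domain", "lifecycle", "excluded")
}

#' The four PDE5-inhibitor active ingredients audited
#' @return Character vector of ingredient labels.
#' @export
audit_apis <- function() c("sildenafil", "tadalafil", "vardenafil", "avanafil")

# Half-up decimal rounding, the convention of printed n (%) tables
# (2.5% -> 3, 1.25% -> 1.3); base round() is half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Categories that may carry a distinct landing/destination domain.
destination_categories <- function() {
  c("active_redirect", "national_illegal_seller", "dietary_supplement_shop")
}

#' Read a SERP audit file
#'
#' Reads a comma-separated UTF-8 audit file (one row per documented search
#' result) into a validated tibble. Rows that fail validation (bad rank, bad
#' enum, bad date, missing destination on an active redirect) are dropped
#' from the result and reported, line-addressed, in the `row_errors`
#' attribute (see [audit_errors()]). A missing mandatory column is an error.
#'
#' @param path Path to a CSV file with a header naming the schema fields.
#'   Mandatory columns: audit_date, country, language, api, search_phrase,
#'   result_url, rank, category. Optional: source_domain, destination_url,
#'   destination_domain, lifecycle, excluded.
#' @param rank_max Maximum admissible rank; a dataset property (20 for the
#'   national top-20 audits, 40 for the international top-40 audit).
#' @return A tibble of validated records in canonical column order, with a
#'   `row_errors` attribute (tibble: line, field, message).
#' @export
read_audit <- function(path, rank_max = 40) {
  mandatory <- c("audit_date", "country", "language", "api", "search_phrase",
                 "result_url", "rank", "category")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("audit schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in setdiff(audit_columns(), names(raw))) raw[[col]] <- NA_character_
  raw <- raw[audit_columns()]
  validate_audit(raw, rank_max = rank_max)
}

#' Validate raw audit rows
#'
#' Coerces column types and applies the schema invariants row by row. Used by
#' [read_audit()]; exposed so in-memory records (e.g. synthetic audits) can be
#' run through the same checks.
#'
#' @param raw A data frame with the audit columns (character or typed).
#' @param rank_max Maximum admissible rank.
#' @return Tibble of valid records with a `row_errors` attribute.
#' @export
validate_audit <- function(raw, rank_max = 40) {
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  errs <- list()
  note <- function(line, field, message) {
    errs[[length(errs) + 1L]] <<- tibble::tibble(line = line, field = field,
                                                 message = message)
  }

  parsed <- suppressWarnings(as.Date(as.character(raw$audit_date), format = "%Y-%m-%d"))
  ok_date <- !is.na(parsed)
  for (i in which(!ok_date)) {
    note(i, "audit_date", paste0("missing or unparseable ISO-8601 date: ", raw$audit_date[i]))
  }
  date <- parsed

  rank <- suppressWarnings(as.integer(as.character(raw$rank)))
  ok_rank <- !is.na(rank) & rank >= 1L & rank <= rank_max
  for (i in which(!ok_rank)) {
    note(i, "rank", paste0("rank must be an integer in [1, ", rank_max, "], got: ", raw$rank[i]))
  }

  cat_chr <- as.character(raw$category)
  ok_cat <- cat_chr %in% link_categories()
  for (i in which(!ok_cat)) note(i, "category", paste0("unknown link category: ", cat_chr[i]))

  api_chr <- tolower(as.character(raw$api))
  ok_api <- api_chr %in% audit_apis()
  for (i in which(!ok_api)) note(i, "api", paste0("unknown API: ", raw$api[i]))

  lc <- as.character(raw$lifecycle)
  ok_lc <- is.na(lc) | lc %in% lifecycle_states()
  for (i in which(!ok_lc)) note(i, "lifecycle", paste0("unknown lifecycle state: ", lc[i]))
  # lifecycle present iff the category is one of the compromised stages
  lc_cat <- cat_chr %in% compromised_categories()
  bad_lc <- ok_cat & ok_lc & (lc_cat != !is.na(lc))
  for (i in which(bad_lc)) {
    note(i, "lifecycle",
         "lifecycle must be present exactly for active_redirect / compromised_no_redirect / not_accessible")
  }
  ok_lc <- ok_lc & !bad_lc

  dest_url <- as.character(raw$destination_url)
  dest_dom <- as.character(raw$destination_domain)
  fill <- is.na(dest_dom) & !is.na(dest_url)
  dest_dom[fill] <- vapply(dest_url[fill], function(u) {
    tryCatch(extract_domain(u), error = function(e) NA_character_)
  }, character(1))
  # destination present iff category can carry one; mandatory for active redirects
  ok_dest <- rep(TRUE, n)
  bad_need <- ok_cat & cat_chr == "active_redirect" & is.na(dest_dom)
  for (i in which(bad_need)) note(i, "destination_domain", "active redirect without a destination")
  bad_have <- ok_cat & !(cat_chr %in% destination_categories()) & !is.na(dest_dom)
  for (i in which(bad_have)) {
    note(i, "destination_domain", paste0("category ", cat_chr[i], " cannot carry a destination"))
  }
  ok_dest <- !bad_need & !bad_have

  src <- as.character(raw$source_domain)
  res_url <- as.character(raw$result_url)
  need_src <- is.na(src)
  src[need_src] <- vapply(res_url[need_src], function(u) {
    tryCatch(extract_domain(u), error = function(e) NA_character_)
  }, character(1))
  ok_src <- !is.na(src)
  for (i in which(!ok_src)) note(i, "result_url", paste0("unparseable result URL: ", res_url[i]))

  excluded <- tolower(as.character(raw$excluded)) %in% c("true", "1", "yes")

  keep <- ok_date & ok_rank & ok_cat & ok_api & ok_lc & ok_dest & ok_src
  out <- tibble::tibble(
    audit_date = date[keep],
    country = toupper(as.character(raw$country)[keep]),
    language = tolower(as.character(raw$language)[keep]),
    api = api_chr[keep],
    search_phrase = as.character(raw$search_phrase)[keep],
    result_url = res_url[keep],
    source_domain = src[keep],
    rank = rank[keep],
    category = cat_chr[keep],
    destination_url = dest_url[keep],
    destination_domain = dest_dom[keep],
    lifecycle = lc[keep],
    excluded = excluded[keep]
  )
  row_errors <- if (length(errs) > 0) dplyr::bind_rows(errs) else
    tibble::tibble(line = integer(), field = character(), message = character())
  attr(out, "row_errors") <- dplyr::arrange(row_errors, .data$line)
  out
}

#' Row-addressed validation errors from an audit read
#'
#' @param records A tibble returned by [read_audit()] or [validate_audit()].
#' @return Tibble with columns line, field, message (empty when all rows parsed).
#' @export
audit_errors <- function(records) {
  e <- attr(records, "row_errors")
  if (is.null(e)) tibble::tibble(line = integer(), field = character(), message = character())
  else e
}

#' Write a SERP audit file in canonical form
#'
#' Writes records as UTF-8 CSV with ISO-8601 dates and canonical column order,
#' so that read-write-read is the identity and a rewritten file byte-compares
#' equal to the canonical form.
#'
#' @param records Validated audit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(records, path) {
  out <- records[audit_columns()]
  out$audit_date <- format(out$audit_date, "%Y-%m-%d")
  out$excluded <- ifelse(out$excluded, "true", "false")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Classify the life-cycle stage of a compromised link
#'
#' Maps the flags observed for a compromised link at evaluation time onto the
#' redirection life cycle: `future` (injected content present but no automatic
#' redirection yet), `active` (redirection to a destination observed), and
#' `inactive` (formerly redirecting but now not redirecting or not accessible,
#' e.g. returning a 404). A link that redirects but is reported inaccessible
#' is a contradictory observation and raises an error.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param has_injected_content Injected (keyword-stuffed) content observed.
#' @param redirects_now Automatic redirection to a destination observed now.
#' @param accessible Page reachable at evaluation time.
#' @param previously_active Link was observed actively redirecting before.
#' @return Character vector of life-cycle states.
#' @export
classify_lifecycle <- function(has_injected_content, redirects_now,
                               accessible, previously_active) {
  n <- max(length(has_injected_content), length(redirects_now),
           length(accessible), length(previously_active))
  inj <- rep_len(as.logical(has_injected_content), n)
  red <- rep_len(as.logical(redirects_now), n)
  acc <- rep_len(as.logical(accessible), n)
  prev <- rep_len(as.logical(previously_active), n)
  if (any(is.na(inj) | is.na(red) | is.na(acc) | is.na(prev))) {
    stop("invalid observation: lifecycle flags must be TRUE/FALSE")
  }
  bad <- red & !acc
  if (any(bad)) {
    stop("invalid observation: redirecting but not accessible (row ",
         paste(which(bad), collapse = ", "), ")")
  }
  out <- rep("future", n)
  out[red] <- "active"
  out[!red & (!acc | prev)] <- "inactive"
  out
}

#' Tabulate link categories (n and %)
#'
#' Counts records per category, optionally within groups (by any of
#' audit_date, country, api), and reports each category's share of the group
#' total. All seven categories are always reported, including zero counts.
#' For an empty group the shares are undefined and reported as 0 with
#' `empty = TRUE`.
#'
#' @param records Validated audit tibble. Rows flagged `excluded` are dropped
#'   before counting.
#' @param group_by Character vector of grouping keys (subset of the record
#'   columns), or empty for one overall table.
#' @param digits Decimal places for the percentage share (default 0, the
#'   convention of n (%) summary tables; use `Inf` for unrounded shares).
#' @return Tibble with the group keys, category, n, total, share, empty.
#' @export
tabulate_categories <- function(records, group_by = character(), digits = 0) {
  bad <- setdiff(group_by, names(records))
  if (length(bad) > 0) {
    stop("configuration error: unknown group key(s): ", paste(bad, collapse = ", "))
  }
  recs <- records[!records$excluded, , drop = FALSE]
  cats <- tibble::tibble(category = factor(link_categories(), levels = link_categories()))
  if (length(group_by) == 0) {
    counts <- dplyr::count(recs, category = factor(.data$category, levels = link_categories()),
                           .drop = FALSE, name = "n")
    counts <- dplyr::left_join(cats, counts, by = "category")
    counts$n[is.na(counts$n)] <- 0L
    groups <- counts
  } else {
    keys <- dplyr::distinct(recs[group_by])
    if (nrow(keys) == 0) keys <- keys[0, , drop = FALSE]
    grid <- tidyr::crossing(keys, cats)
    counts <- dplyr::count(recs, dplyr::across(dplyr::all_of(group_by)),
                           category = factor(.data$category, levels = link_categories()),
                           name = "n")
    groups <- dplyr::left_join(grid, counts, by = c(group_by, "category"))
    groups$n[is.na(groups$n)] <- 0L
  }
  groups <- dplyr::group_by(groups, dplyr::across(dplyr::all_of(group_by)))
  groups <- dplyr::mutate(groups,
    total = sum(.data$n),
    empty = .data$total == 0L,
    share = ifelse(.data$total == 0L, 0, 100 * .data$n / .data$total)
  )
  groups <- dplyr::ungroup(groups)
  if (is.finite(digits)) groups$share <- round_half_up(groups$share, digits)
  groups$category <- as.character(groups$category)
  groups
}

#' Render a category breakdown in n (%) style
#'
#' @param tab A breakdown from [tabulate_categories()].
#' @return The tibble with an added `n_pct` column like `"43 (54)"`.
#' @export
render_breakdown <- function(tab) {
  tab$n_pct <- sprintf("%d (%s)", tab$n, format(tab$share, trim = TRUE))
  tab
}

#' Export a category breakdown as JSON
#'
#' @param tab A breakdown from [tabulate_categories()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_breakdown_json <- function(tab, path) {
  jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
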
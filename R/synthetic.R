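#' Configuration of the synthetic SERP-audit generator
#'
#' Parameterizes a seeded generator of synthetic search-audit datasets with
#' the statistical structure of a pharmacy-poisoning affiliate network: a
#' configurable fraction of compromised results, a hub-dominated destination
#' attachment (Zipf), source infections that promote one or several active
#' ingredients, per-source fan-out to one or more destinations, and a
#' geometric infection life cycle.
#'
#' The defaults encode a 12-country, 4-ingredient, top-40 audit (1920
#' evaluated results) with 19.8% compromised links of which 90% actively
#' redirect, 73 candidate destination domains with Zipf exponent 1 (the top-3
#' destinations then expect over a third of all incoming links), 69.6% of
#' source infections feeding a single destination with mean fan-out 1.49,
#' 28.3% of sources promoting more than one ingredient, and a median
#' infection survival of 19 days.
#'
#' @param countries ISO-3166 country codes audited.
#' @param languages Search-language tags, parallel to `countries`.
#' @param apis Active-ingredient labels (the four PDE5 inhibitors).
#' @param rank_max Organic positions documented per query (20 or 40).
#' @param prevalence Probability that an evaluated result is compromised.
#' @param compromised_mix Category distribution conditional on compromised
#'   (active_redirect / compromised_no_redirect / not_accessible).
#' @param benign_mix Category distribution conditional on not compromised.
#' @param n_destinations Size of the destination-domain pool.
#' @param hub_skew Zipf exponent of destination attachment (> 0).
#' @param single_dest_frac Fraction of source infections feeding exactly one
#'   destination.
#' @param fanout_mean Mean distinct destinations per source (>= 1).
#' @param extra_links_rate Poisson rate of additional links a source emits
#'   beyond one per distinct destination (controls links per source).
#' @param multi_api_source_frac Fraction of sources promoting > 1 ingredient.
#' @param survival_median_days Median survival of an active infection.
#' @param heavy_tail Use a two-component survival mixture with a persistent
#'   subpopulation instead of a single geometric.
#' @param heavy_frac,heavy_median_days Persistent-component weight and
#'   median; the defaults make about 17% of infections survive 6 months and
#'   8% survive a year while the overall median stays at
#'   `survival_median_days`.
#' @param activation_median_days Median days for a future redirect to turn
#'   active.
#' @param inactive_split Probabilities that a dying active infection becomes
#'   `not_accessible` vs `compromised_no_redirect`.
#' @param rogue_frac,legit_mix Destination legitimacy mix; `rogue_frac`
#'   overrides the rogue mass of `legit_mix`.
#' @param visitors_range Log-uniform range of monthly unique visitors.
#' @param visitors_missing_frac Fraction of destinations without traffic data.
#' @param pharmacy_named_frac Fraction of destination domains carrying a
#'   pharmacy-flavoured name.
#' @param audit_date Nominal date of the generated snapshot.
#' @param seed Integer seed governing every random stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    countries = c("BG", "HR", "EE", "FI", "FR", "GR", "HU", "IT", "RO", "ES", "SE", "GB"),
    languages = c("bg", "hr", "et", "fi", "fr", "el", "hu", "it", "ro", "es", "sv", "en"),
    apis = audit_apis(),
    rank_max = 40L,
    prevalence = 0.198,
    compromised_mix = c(active_redirect = 0.90, compromised_no_redirect = 0.016,
                        not_accessible = 0.084),
    benign_mix = c(legitimate_pharmacy = 0, national_illegal_seller = 0.27,
                   dietary_supplement_shop = 0.30, other_non_seller = 0.43),
    n_destinations = 73L,
    hub_skew = 1.0,
    single_dest_frac = 0.696,
    fanout_mean = 1.49,
    extra_links_rate = 0.16,
    multi_api_source_frac = 0.283,
    survival_median_days = 19,
    heavy_tail = FALSE,
    heavy_frac = 0.354,
    heavy_median_days = 170,
    activation_median_days = 19,
    inactive_split = c(not_accessible = 0.84, compromised_no_redirect = 0.16),
    rogue_frac = 0.79,
    legit_mix = c(approved = 0.01, unlicensed = 0.05, rogue = 0.79,
                  not_in_database = 0.15),
    visitors_range = c(300, 600000),
    visitors_missing_frac = 0.45,
    pharmacy_named_frac = 0.875,
    audit_date = as.Date("2020-11-15"),
    seed = 1L) {
  if (length(languages) != length(countries)) {
    stop("configuration error: languages must be parallel to countries")
  }
  if (prevalence < 0 || prevalence > 1) {
    stop("configuration error: prevalence must lie in [0, 1]")
  }
  if (hub_skew <= 0) stop("configuration error: hub_skew must be > 0")
  if (fanout_mean < 1) stop("configuration error: fanout_mean must be >= 1")
  if (single_dest_frac < 0 || single_dest_frac > 1) {
    stop("configuration error: single_dest_frac must lie in [0, 1]")
  }
  if (single_dest_frac == 1 && fanout_mean > 1) {
    stop("configuration error: single_dest_frac = 1 is inconsistent with fanout_mean > 1")
  }
  if (rank_max < 1) stop("configuration error: rank_max must be >= 1")
  compromised_mix <- compromised_mix / sum(compromised_mix)
  benign_mix <- benign_mix / sum(benign_mix)
  legit_mix["rogue"] <- rogue_frac
  legit_mix[setdiff(names(legit_mix), "rogue")] <-
    legit_mix[setdiff(names(legit_mix), "rogue")] /
    sum(legit_mix[setdiff(names(legit_mix), "rogue")]) * (1 - rogue_frac)
  inactive_split <- inactive_split / sum(inactive_split)

  # fan-out: K = 1 with prob single_dest_frac, else 1 + zero-truncated
  # Poisson(lambda); solve lambda so that E[K] = fanout_mean
  lambda_fanout <- 0
  if (single_dest_frac < 1 && fanout_mean > 1) {
    target <- (fanout_mean - 1) / (1 - single_dest_frac)  # = E[ZTP]
    if (target < 1) {
      stop("configuration error: fanout_mean too small for single_dest_frac ",
           "(implied multi-destination mean below 2 destinations)")
    }
    lambda_fanout <- stats::uniroot(
      function(l) l / (1 - exp(-l)) - target, c(1e-9, 100), tol = 1e-12)$root
  } else if (fanout_mean > 1) {
    stop("configuration error: cannot reach fanout_mean > 1 with single_dest_frac = 1")
  }
  # multi-API flag can only be realised by sources with >= 2 links; rescale
  # the flag probability so the marginal matches multi_api_source_frac
  p_one_link <- single_dest_frac * exp(-extra_links_rate)
  p_multi_adj <- if (multi_api_source_frac == 0) 0 else
    multi_api_source_frac / (1 - p_one_link)
  if (is.nan(p_multi_adj) || p_multi_adj > 1) {
    stop("configuration error: multi_api_source_frac unreachable given ",
         "single_dest_frac and extra_links_rate")
  }
  # heavy-tail survival: calibrate the base median so the mixture median
  # stays at survival_median_days
  base_median <- survival_median_days
  if (heavy_tail) {
    f <- function(m) {
      (1 - heavy_frac) * 0.5^(survival_median_days / m) +
        heavy_frac * 0.5^(survival_median_days / heavy_median_days) - 0.5
    }
    if (f(survival_median_days) >= 0) {
      base_median <- stats::uniroot(f, c(1e-6, survival_median_days), tol = 1e-10)$root
    }
  }
  structure(list(
    countries = countries, languages = languages, apis = apis,
    rank_max = as.integer(rank_max), prevalence = prevalence,
    compromised_mix = compromised_mix, benign_mix = benign_mix,
    n_destinations = as.integer(n_destinations), hub_skew = hub_skew,
    single_dest_frac = single_dest_frac, fanout_mean = fanout_mean,
    lambda_fanout = lambda_fanout, extra_links_rate = extra_links_rate,
    multi_api_source_frac = multi_api_source_frac, p_multi_adj = p_multi_adj,
    survival_median_days = survival_median_days, heavy_tail = heavy_tail,
    heavy_frac = heavy_frac, heavy_median_days = heavy_median_days,
    base_median = base_median,
    activation_median_days = activation_median_days,
    inactive_split = inactive_split, legit_mix = legit_mix,
    visitors_range = visitors_range,
    visitors_missing_frac = visitors_missing_frac,
    pharmacy_named_frac = pharmacy_named_frac,
    audit_date = as.Date(audit_date), seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Independent seed per named stream so stages regenerate independently of
# each other (destination pool, slot flags, network assembly, ...).
stream_seed <- function(seed, stream) {
  strtoi(substr(rlang::hash(list(as.integer(seed), stream)), 1, 7), 16L)
}

zipf_weights <- function(n, s) (seq_len(n))^(-s) / sum((seq_len(n))^(-s))

rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  out <- stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  pmax(out, 1L)
}

country_tld <- function(country) {
  ifelse(toupper(country) == "GB", "co.uk", tolower(country))
}

# Deterministic destination-domain pool for a config (own stream).
dest_domains <- function(config) {
  n <- config$n_destinations
  if (n == 0) return(character(0))
  old <- globalenv()$.Random.seed
  set.seed(stream_seed(config$seed, "destinations"))
  on.exit(restore_seed(old), add = TRUE)
  n_pharm <- round(config$pharmacy_named_frac * n)
  a <- c("rx", "pharm", "meds", "pills", "drugs", "medi")
  b <- c("store", "shop", "online", "24h", "direct", "global", "group", "hub")
  pharm <- sprintf("%s-%s-%02d.com", sample(a, n_pharm, replace = TRUE),
                   sample(b, n_pharm, replace = TRUE), seq_len(n_pharm))
  w1 <- c("forecast", "sunny", "harbor", "mosaic", "violet", "cedar", "quartz")
  w2 <- c("arrays", "fields", "works", "lines", "crest", "grove")
  n_plain <- n - n_pharm
  plain <- if (n_plain > 0) {
    sprintf("%s%s-%02d.%s", sample(w1, n_plain, replace = TRUE),
            sample(w2, n_plain, replace = TRUE), seq_len(n_plain),
            sample(c("com", "us", "net"), n_plain, replace = TRUE))
  } else character(0)
  doms <- c(pharm, plain)
  doms[sample.int(n)]
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

benign_domain <- function(i, country) {
  w1 <- c("garden", "travel", "foto", "alpine", "craft", "bakery", "hobby",
          "nature", "retro", "silver")
  w2 <- c("blog", "club", "studio", "works", "zone", "corner", "house", "post")
  sprintf("%s-%s-%03d.%s", w1[(i %% length(w1)) + 1L], w2[(i %/% 7L) %% length(w2) + 1L],
          i, country_tld(country))
}

source_domain_name <- function(i, country) {
  w1 <- c("kert", "sun", "city", "green", "nord", "villa", "atelier", "museo",
          "radio", "vista")
  w2 <- c("portal", "site", "page", "web", "press", "news", "info-hub", "gallery")
  sprintf("%s-%s-%03d.%s", w1[(i %% length(w1)) + 1L], w2[(i %/% 11L) %% length(w2) + 1L],
          i, country_tld(country))
}

#' Generate a synthetic SERP audit snapshot
#'
#' Draws, for every country x ingredient query, `rank_max` documented organic
#' results; marks each compromised independently with probability
#' `prevalence`; assigns compromised results a category from the compromised
#' mix and benign results from the benign mix; and wires active redirects
#' into an affiliate network: source infections are assembled so that the
#' configured single-destination fraction, mean fan-out, and multi-ingredient
#' fraction hold in expectation, and each source's destinations are drawn
#' without replacement from a Zipf-weighted destination pool (hub
#' dominance). Fully reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A validated audit tibble (see [read_audit()] for the schema) with
#'   the config attached as attribute `config`.
#' @export
generate_audit <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)

  slots <- tidyr::crossing(
    tibble::tibble(country = config$countries, language = config$languages),
    tibble::tibble(api = config$apis),
    tibble::tibble(rank = seq_len(config$rank_max))
  )
  n <- nrow(slots)

  set.seed(stream_seed(config$seed, "slots"))
  compromised <- stats::runif(n) < config$prevalence
  slots$category <- NA_character_
  if (any(compromised)) {
    slots$category[compromised] <- sample(names(config$compromised_mix),
                                          sum(compromised), replace = TRUE,
                                          prob = config$compromised_mix)
  }
  if (any(!compromised)) {
    slots$category[!compromised] <- sample(names(config$benign_mix),
                                           sum(!compromised), replace = TRUE,
                                           prob = config$benign_mix)
  }

  dests <- dest_domains(config)
  zw <- zipf_weights(config$n_destinations, config$hub_skew)

  slots$source_domain <- NA_character_
  slots$destination_domain <- NA_character_
  slots$lifecycle <- NA_character_

  # benign results and non-active hacked pages get standalone domains
  set.seed(stream_seed(config$seed, "benign"))
  idx_benign <- which(!compromised)
  slots$source_domain[idx_benign] <-
    benign_domain(seq_along(idx_benign), slots$country[idx_benign])
  idx_hacked_inactive <- which(slots$category %in%
                                 c("compromised_no_redirect", "not_accessible"))
  slots$source_domain[idx_hacked_inactive] <-
    source_domain_name(900L + seq_along(idx_hacked_inactive),
                       slots$country[idx_hacked_inactive])
  slots$lifecycle[slots$category == "compromised_no_redirect"] <- "future"
  slots$lifecycle[slots$category == "not_accessible"] <- "inactive"

  # Affiliate assembly of active redirects, per country. Source plans (K
  # distinct destinations, m links, multi-ingredient flag) are drawn from the
  # calibrated distributions; when the remaining slot pool of a country is
  # too small to realise a plan, the leftover slots are attached as extra
  # links to existing compatible sources (same ingredient for single-API
  # sources, reusing one of the source's destinations), which leaves the
  # calibrated per-source statistics unchanged instead of creating truncated
  # sources.
  set.seed(stream_seed(config$seed, "network"))
  src_counter <- 0L
  sample1 <- function(x, n = 1, ...) if (length(x) == 1) rep(x, n) else sample(x, n, ...)
  for (ctry in config$countries) {
    remaining <- which(slots$country == ctry & slots$category == "active_redirect")
    sources <- list()
    attach_leftovers <- function(idx) {
      for (slot in idx) {
        api <- slots$api[slot]
        cand <- which(vapply(sources, function(s) s$multi || api %in% s$apis,
                             logical(1)))
        if (length(cand) > 0) {
          pick <- sources[[sample1(cand)]]
          slots$source_domain[slot] <<- pick$name
          slots$destination_domain[slot] <<- dests[sample1(pick$dset)]
        } else {
          src_counter <<- src_counter + 1L
          d <- sample.int(config$n_destinations, 1, prob = zw)
          slots$source_domain[slot] <<- source_domain_name(src_counter, ctry)
          slots$destination_domain[slot] <<- dests[d]
          sources[[length(sources) + 1L]] <<-
            list(name = slots$source_domain[slot], multi = FALSE,
                 apis = api, dset = d)
        }
        slots$lifecycle[slot] <<- "active"
      }
    }
    while (length(remaining) > 0) {
      K <- if (stats::runif(1) < config$single_dest_frac) 1L else
        1L + rztpois(1, config$lambda_fanout)
      m <- K + stats::rpois(1, config$extra_links_rate)
      if (m > length(remaining)) {
        attach_leftovers(remaining)
        remaining <- integer(0)
        break
      }
      api_counts <- table(slots$api[remaining])
      multi_ok <- m >= 2 && length(api_counts) >= 2
      multi <- multi_ok && stats::runif(1) < config$p_multi_adj
      if (multi) {
        n_apis <- min(sample(2:4, 1, prob = c(0.7, 0.2, 0.1)),
                      length(api_counts), m)
        chosen <- sample(names(api_counts), n_apis, prob = as.numeric(api_counts))
        picked <- vapply(chosen, function(a) {
          sample1(remaining[slots$api[remaining] == a])
        }, integer(1))
        rest_pool <- setdiff(remaining, picked)
        extra_n <- min(m - length(picked), length(rest_pool))
        picked <- c(picked, if (extra_n > 0) sample1(rest_pool, extra_n) else integer(0))
      } else {
        ok <- names(api_counts)[api_counts >= m]
        if (length(ok) == 0) {
          # balanced pool with a large plan: attach the deficit later
          a <- names(api_counts)[which.max(api_counts)]
          m <- max(api_counts)
          K <- min(K, m)
        } else {
          a <- sample1(ok, prob = as.numeric(api_counts[ok]))
        }
        picked <- sample1(remaining[slots$api[remaining] == a], m)
      }
      m <- length(picked)
      K <- min(K, m)
      src_counter <- src_counter + 1L
      dset <- sample.int(config$n_destinations, K, prob = zw)
      dest_per_link <- c(dset, if (m > K)
        dset[sample.int(K, m - K, replace = TRUE)] else integer(0))
      dest_per_link <- dest_per_link[sample.int(m)]
      nm <- source_domain_name(src_counter, ctry)
      slots$source_domain[picked] <- nm
      slots$destination_domain[picked] <- dests[dest_per_link]
      slots$lifecycle[picked] <- "active"
      apis_used <- unique(slots$api[picked])
      sources[[length(sources) + 1L]] <-
        list(name = nm, multi = length(apis_used) > 1, apis = apis_used, dset = dset)
      remaining <- setdiff(remaining, picked)
    }
  }

  phrase_buy <- c(bg = "kupi", hr = "kupiti", et = "osta", fi = "osta",
                  fr = "acheter", el = "agora", hu = "vasarlas", it = "comprare",
                  ro = "cumpara", es = "comprar", sv = "kopa", en = "buy")
  buy <- phrase_buy[slots$language]
  buy[is.na(buy)] <- "buy"
  out <- tibble::tibble(
    audit_date = config$audit_date,
    country = slots$country,
    language = slots$language,
    api = slots$api,
    search_phrase = paste(unname(buy), slots$api),
    result_url = paste0("http://", slots$source_domain, "/p", slots$rank),
    source_domain = slots$source_domain,
    rank = slots$rank,
    category = slots$category,
    destination_url = ifelse(is.na(slots$destination_domain), NA_character_,
                             paste0("https://", slots$destination_domain, "/")),
    destination_domain = slots$destination_domain,
    lifecycle = slots$lifecycle,
    excluded = FALSE
  )
  out <- validate_audit(out, rank_max = config$rank_max)
  if (nrow(audit_errors(out)) > 0) {
    stop("internal error: generated audit failed validation")
  }
  attr(out, "config") <- config
  out
}

survival_prob <- function(config, elapsed_days, persistent) {
  if (config$heavy_tail) {
    ifelse(persistent, 0.5^(elapsed_days / config$heavy_median_days),
           0.5^(elapsed_days / config$base_median))
  } else {
    rep(0.5^(elapsed_days / config$survival_median_days), length(persistent))
  }
}

#' Evolve an audit snapshot through the infection life cycle
#'
#' Advances every compromised result by `elapsed_days`: active redirections
#' survive with a memoryless (geometric) per-day hazard calibrated so the
#' median survival equals `survival_median_days` (optionally a two-component
#' mixture with a persistent subpopulation); non-survivors transition to
#' `not_accessible` or `compromised_no_redirect` per `inactive_split` and
#' lose their destination; future redirects activate with a geometric hazard
#' with median `activation_median_days` and receive a destination drawn from
#' the Zipf-weighted pool. Benign results are untouched. `elapsed_days = 0`
#' is the identity.
#'
#' @param records An audit tibble from [generate_audit()] or a previous
#'   snapshot (the generator config is read from the `config` attribute
#'   unless supplied).
#' @param elapsed_days Non-negative number of days to advance.
#' @param config A [synthetic_config()]; defaults to the records' attribute.
#' @return The evolved audit tibble, dated `elapsed_days` later.
#' @export
evolve_snapshot <- function(records, elapsed_days, config = attr(records, "config")) {
  if (is.null(config)) stop("no generator config supplied or attached to records")
  if (elapsed_days < 0) stop("domain error: elapsed_days must be >= 0")
  if (elapsed_days == 0) return(records)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(stream_seed(config$seed, paste0("evolve-", elapsed_days)))

  out <- records
  out$audit_date <- out$audit_date + elapsed_days

  active <- which(out$category == "active_redirect")
  future <- which(out$category == "compromised_no_redirect")
  if (length(active) > 0) {
    persistent <- stats::runif(length(active)) < config$heavy_frac
    surv <- stats::runif(length(active)) <
      survival_prob(config, elapsed_days, persistent)
    dying <- active[!surv]
    if (length(dying) > 0) {
      out$category[dying] <- sample(names(config$inactive_split), length(dying),
                                    replace = TRUE, prob = config$inactive_split)
      out$lifecycle[dying] <- ifelse(out$category[dying] == "not_accessible",
                                     "inactive", "future")
      out$destination_url[dying] <- NA_character_
      out$destination_domain[dying] <- NA_character_
    }
  }

  if (length(future) > 0) {
    p_act <- 1 - 0.5^(elapsed_days / config$activation_median_days)
    turning <- future[stats::runif(length(future)) < p_act]
    if (length(turning) > 0) {
      dests <- dest_domains(config)
      zw <- zipf_weights(config$n_destinations, config$hub_skew)
      d <- dests[sample.int(config$n_destinations, length(turning),
                            replace = TRUE, prob = zw)]
      out$category[turning] <- "active_redirect"
      out$lifecycle[turning] <- "active"
      out$destination_domain[turning] <- d
      out$destination_url[turning] <- paste0("https://", d, "/")
    }
  }
  attr(out, "config") <- config
  attr(out, "row_errors") <- attr(records, "row_errors")
  out
}

#' Generate synthetic destination-domain profiles
#'
#' Builds the legitimacy / traffic metadata table for the configured
#' destination pool: legitimacy is sampled with a rogue-dominant mix,
#' monthly unique visitors are log-uniform over `visitors_range`, a
#' configured fraction of domains lack visitor data, and the pharmacy-named
#' flag is computed from the domain itself.
#'
#' @param config A [synthetic_config()].
#' @return Tibble: domain, legitimacy, monthly_unique_visitors,
#'   pharmacy_named.
#' @export
generate_destination_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  doms <- dest_domains(config)
  if (length(doms) == 0) {
    return(tibble::tibble(domain = character(), legitimacy = character(),
                          monthly_unique_visitors = numeric(),
                          pharmacy_named = logical()))
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(stream_seed(config$seed, "profiles"))
  n <- length(doms)
  legit <- sample(names(config$legit_mix), n, replace = TRUE,
                  prob = config$legit_mix)
  lv <- log(config$visitors_range)
  visitors <- round(exp(stats::runif(n, lv[1], lv[2])))
  visitors[stats::runif(n) < config$visitors_missing_frac] <- NA
  tibble::tibble(
    domain = doms,
    legitimacy = legit,
    monthly_unique_visitors = as.numeric(visitors),
    pharmacy_named = pharmacy_named(doms)
  )
}

#' Per-source affiliate statistics of an audit
#'
#' Summarises the source infections of an audit's active redirects: links
#' emitted, distinct destinations (fan-out), and whether the source promotes
#' more than one active ingredient. These are the quantities the generator
#' calibrates, so pushing a synthetic audit through this summary recovers
#' the configured single-destination fraction, mean fan-out, and
#' multi-ingredient fraction.
#'
#' @param records Validated audit tibble.
#' @return Tibble: source_domain, n_links, n_destinations, n_apis, multi_api,
#'   single_destination.
#' @export
source_summary <- function(records) {
  act <- records[records$category == "active_redirect", , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(act, .data$source_domain),
    n_links = dplyr::n(),
    n_destinations = dplyr::n_distinct(.data$destination_domain),
    n_apis = dplyr::n_distinct(.data$api),
    multi_api = n_apis > 1L,
    single_destination = n_destinations == 1L,
    .groups = "drop"
  )
}
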
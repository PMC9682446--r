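# Snapshot of common public-suffix rules. Single-label TLDs need no listing:
# any unknown final label is treated as the suffix. Multi-label entries are
# the ones that change the registrable cut (e.g. example.co.uk registers at
# three labels, not two).
multi_label_suffixes <- function() {
  c("co.uk", "org.uk", "ac.uk", "gov.uk", "me.uk", "net.uk", "ltd.uk", "plc.uk", "sch.uk",
    "co.jp", "or.jp", "ne.jp", "ac.jp", "go.jp", "ad.jp",
    "com.au", "net.au", "org.au", "edu.au", "gov.au", "id.au",
    "co.nz", "net.nz", "org.nz", "ac.nz", "govt.nz",
    "co.in", "net.in", "org.in", "firm.in", "gen.in", "ind.in",
    "co.za", "net.za", "org.za", "web.za",
    "com.br", "net.br", "org.br", "gov.br",
    "com.cn", "net.cn", "org.cn", "gov.cn", "edu.cn",
    "com.mx", "org.mx", "net.mx",
    "com.ar", "com.tr", "com.sg", "com.hk", "com.tw", "com.my", "com.ph",
    "co.kr", "or.kr", "ne.kr", "re.kr",
    "com.ua", "net.ua", "org.ua", "in.ua",
    "com.pl", "net.pl", "org.pl", "edu.pl", "waw.pl",
    "com.ru", "net.ru", "org.ru", "msk.ru", "spb.ru",
    "co.il", "org.il", "ac.il",
    "com.eg", "com.sa", "com.pk", "com.bd", "com.vn", "com.ng",
    "co.th", "in.th", "ac.th",
    "co.id", "or.id", "ac.id", "web.id",
    "com.gr", "edu.gr", "net.gr", "org.gr",
    "com.ro", "org.ro", "nt.ro",
    "com.bg", "com.hr", "com.ee", "com.es", "org.es", "nom.es",
    "com.pt", "org.pt", "edu.pt")
}

#' Extract the registrable domain from a URL
#'
#' Reduces an absolute URL to its lower-cased registrable domain, aware of
#' multi-label public suffixes (so `https://blog.example.co.uk/p` yields
#' `example.co.uk`, not `co.uk`). The result is stable across scheme, case,
#' port, path and query variants, which is what lets compromised pages living
#' on subdomains and subpaths of one hacked site aggregate to a single source
#' domain. Suffix matching uses an embedded snapshot of common public-suffix
#' rules; unknown final labels are treated as single-label suffixes.
#'
#' @param url Character vector of absolute URLs (scheme required) or bare
#'   host names containing at least one dot.
#' @return Character vector of registrable domains.
#' @export
extract_domain <- function(url) {
  vapply(as.character(url), extract_domain1, character(1), USE.NAMES = FALSE)
}

extract_domain1 <- function(url) {
  if (is.na(url) || !nzchar(url)) stop("parse error: empty URL")
  u <- trimws(url)
  host <- if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", u)) {
    sub("^[A-Za-z][A-Za-z0-9+.-]*://", "", u)
  } else if (grepl("^//", u)) {
    sub("^//", "", u)
  } else if (grepl("^[A-Za-z0-9._-]+\\.[A-Za-z0-9-]+$", u)) {
    u  # bare host
  } else {
    stop("parse error: not an absolute URL: ", url)
  }
  host <- sub("[/?#].*$", "", host)       # drop path/query/fragment
  host <- sub("^[^@]*@", "", host)        # drop userinfo
  host <- sub(":[0-9]+$", "", host)       # drop port
  host <- tolower(sub("\\.$", "", host))  # drop trailing dot, normalise case
  if (!nzchar(host) || !grepl("^[a-z0-9._-]+$", host)) {
    stop("parse error: invalid host in URL: ", url)
  }
  if (grepl("^[0-9]{1,3}(\\.[0-9]{1,3}){3}$", host)) return(host)  # IPv4 literal
  labels <- strsplit(host, ".", fixed = TRUE)[[1]]
  if (length(labels) < 2) stop("parse error: host has no registrable domain: ", url)
  # longest-match against the multi-label snapshot, else the final label
  suffix_len <- suffix_label_count(labels)
  take <- min(length(labels), suffix_len + 1L)
  paste(utils::tail(labels, take), collapse = ".")
}

suffix_label_count <- function(labels) {
  kmax <- min(length(labels) - 1L, 3L)
  if (kmax >= 2L) {
    for (k in seq(kmax, 2L)) {
      if (paste(utils::tail(labels, k), collapse = ".") %in% multi_label_suffixes()) {
        return(k)
      }
    }
  }
  1L
}

# Label portion of a registrable domain (public suffix stripped), used for
# pharmacy-name matching.
domain_label <- function(domain) {
  vapply(as.character(domain), function(d) {
    d <- tolower(d)
    labels <- strsplit(d, ".", fixed = TRUE)[[1]]
    if (length(labels) < 2) return(d)
    paste(utils::head(labels, length(labels) - suffix_label_count(labels)),
          collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}
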
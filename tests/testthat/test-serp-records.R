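test_that("audit CSV read/write round-trips and is byte-stable", {
  recs <- dplyr::bind_rows(
    audit_row(rank = 1, category = "active_redirect",
              destination = "acs-pharmacy.com", lifecycle = "active"),
    audit_row(rank = 2, category = "dietary_supplement_shop",
              source = "vitamin-shop.hu"),
    audit_row(rank = 3, category = "other_non_seller", source = "blog-site.hu")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_audit(validate_audit(recs, rank_max = 20), f)
  rd <- read_audit(f, rank_max = 20)
  expect_equal(nrow(rd), 3L)
  expect_equal(nrow(audit_errors(rd)), 0L)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_audit(rd, f2)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))
  rd2 <- read_audit(f2, rank_max = 20)
  expect_equal(as.data.frame(rd2), as.data.frame(rd))
})

test_that("invalid rows are rejected with line-addressed errors, valid rows kept", {
  recs <- dplyr::bind_rows(
    audit_row(rank = 1),
    audit_row(rank = 0),                              # bad rank
    audit_row(rank = 3),
    audit_row(rank = 4, category = "weird_category")  # bad enum
  )
  f <- withr::local_tempfile(fileext = ".csv")
  out <- recs
  out$audit_date <- format(out$audit_date)
  readr::write_csv(out, f)
  rd <- read_audit(f, rank_max = 20)
  expect_equal(nrow(rd), 2L)
  errs <- audit_errors(rd)
  expect_setequal(errs$line, c(2L, 4L))
  expect_match(errs$message[errs$line == 2L], "rank")
  expect_match(errs$message[errs$line == 4L], "category")
})

test_that("a missing mandatory column is a schema error", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(country = "HU", rank = 1), f)
  expect_error(read_audit(f), "missing mandatory column")
})

test_that("rank bounds are a dataset property", {
  r21 <- audit_row(rank = 21)
  expect_equal(nrow(validate_audit(r21, rank_max = 20)), 0L)
  expect_equal(nrow(validate_audit(r21, rank_max = 40)), 1L)
})

test_that("destination presence follows the category contract", {
  # active redirect without destination: rejected
  bad <- audit_row(category = "active_redirect", lifecycle = "active")
  v <- validate_audit(bad, rank_max = 20)
  expect_equal(nrow(v), 0L)
  expect_match(audit_errors(v)$message, "destination")
  # non-seller carrying a destination: rejected
  bad2 <- audit_row(category = "other_non_seller", destination = "pharm-x.com")
  expect_equal(nrow(validate_audit(bad2, rank_max = 20)), 0L)
  # lifecycle must be present exactly for the compromised categories
  bad3 <- audit_row(category = "other_non_seller", lifecycle = "active")
  expect_equal(nrow(validate_audit(bad3, rank_max = 20)), 0L)
  bad4 <- audit_row(category = "not_accessible")
  expect_equal(nrow(validate_audit(bad4, rank_max = 20)), 0L)
})

test_that("lifecycle classification follows the redirection life cycle", {
  # injected content, no redirection yet: future
  expect_equal(classify_lifecycle(TRUE, FALSE, TRUE, FALSE), "future")
  # observed redirection: active regardless of history or content
  expect_equal(classify_lifecycle(FALSE, TRUE, TRUE, FALSE), "active")
  expect_equal(classify_lifecycle(TRUE, TRUE, TRUE, TRUE), "active")
  # previously active, no longer redirecting or gone: inactive
  expect_equal(classify_lifecycle(FALSE, FALSE, FALSE, TRUE), "inactive")
  expect_equal(classify_lifecycle(TRUE, FALSE, TRUE, TRUE), "inactive")
  expect_equal(classify_lifecycle(FALSE, FALSE, FALSE, FALSE), "inactive")
  # contradictory observation
  expect_error(classify_lifecycle(FALSE, TRUE, FALSE, FALSE), "invalid observation")
})

test_that("lifecycle classification is total and never active without redirection", {
  flags <- expand.grid(inj = c(TRUE, FALSE), red = c(TRUE, FALSE),
                       acc = c(TRUE, FALSE), prev = c(TRUE, FALSE))
  ok <- !(flags$red & !flags$acc)
  res <- classify_lifecycle(flags$inj[ok], flags$red[ok], flags$acc[ok], flags$prev[ok])
  expect_true(all(res %in% c("future", "active", "inactive")))
  expect_true(all(res[!flags$red[ok]] != "active"))
  expect_true(all(res[flags$red[ok]] == "active"))
})

test_that("category tabulation reproduces an n (%) summary table", {
  tab <- tabulate_categories(national_aug2019_audit())
  got <- stats::setNames(tab$share, tab$category)
  expect_equal(got[["active_redirect"]], 54)
  expect_equal(got[["national_illegal_seller"]], 10)
  expect_equal(got[["compromised_no_redirect"]], 6)
  expect_equal(got[["not_accessible"]], 3)
  expect_equal(got[["dietary_supplement_shop"]], 11)
  expect_equal(got[["other_non_seller"]], 16)
  expect_equal(got[["legitimate_pharmacy"]], 0)
  expect_equal(sum(tab$n), 80L)
  rb <- render_breakdown(tab)
  expect_equal(rb$n_pct[rb$category == "active_redirect"], "43 (54)")
})

test_that("tabulation invariants: counts sum to group totals, raw shares to 100", {
  set.seed(42)
  recs <- dplyr::bind_rows(lapply(1:120, function(i) {
    audit_row(rank = (i - 1) %% 20 + 1,
              category = sample(setdiff(link_categories(),
                                        c("active_redirect", "compromised_no_redirect",
                                          "not_accessible")), 1),
              country = sample(c("HU", "ES"), 1),
              api = sample(audit_apis(), 1))
  }))
  recs <- validate_audit(recs, rank_max = 20)
  tab <- tabulate_categories(recs, group_by = c("country", "api"), digits = Inf)
  sums <- dplyr::summarise(dplyr::group_by(tab, country, api),
                           n = sum(n), share = sum(share), total = dplyr::first(total))
  expect_equal(sums$n, sums$total)
  expect_equal(sums$share, rep(100, nrow(sums)))
})

test_that("degenerate tabulations: empty groups and single-category audits", {
  one_cat <- audit_with_counts(c(other_non_seller = 10))
  tab <- tabulate_categories(one_cat)
  expect_equal(tab$share[tab$category == "other_non_seller"], 100)
  empty <- one_cat[0, , drop = FALSE]
  tab0 <- tabulate_categories(empty)
  expect_true(all(tab0$n == 0))
  expect_true(all(tab0$share == 0))
  expect_true(all(tab0$empty))
  expect_error(tabulate_categories(one_cat, group_by = "no_such_key"),
               "unknown group key")
})

test_that("registrable-domain extraction is public-suffix aware and stable", {
  expect_equal(extract_domain("https://acs-pharmacy.com/buy?x=1"), "acs-pharmacy.com")
  expect_equal(extract_domain("http://ACS-PHARMACY.COM/"), "acs-pharmacy.com")
  expect_equal(extract_domain("https://blog.example.co.uk/p"), "example.co.uk")
  # stability across scheme/path/port/query variants
  variants <- c("http://www.evo-pharmacy.com", "https://evo-pharmacy.com:8080/x",
                "ftp://a.b.evo-pharmacy.com/deep/path?q=1#frag")
  expect_equal(unique(extract_domain(variants)), "evo-pharmacy.com")
  expect_equal(extract_domain("http://10.0.0.1/x"), "10.0.0.1")
  expect_error(extract_domain("not a url"), "parse error")
  expect_error(extract_domain(""), "parse error")
})
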
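test_that("annual class counts match a hand tally and conserve totals", {
  cs <- toy_casrns()
  corp <- toy_corpus()
  prof <- build_profiles(corp)
  tx <- class_taxonomy(list(chemical_list("metal", cs[1]),
                            chemical_list("PCB", cs[2])))
  prof <- assign_classes(prof, tx)$profiles
  trend <- annual_class_counts(corp, prof)
  # hand-computed: metal (cs1) in r1, r2 (1999) and r3 (2001);
  # PCB (cs2) in r3, r4 (2001) and r5 (2005); cs3 uncharacterized in r5
  expect_equal(trend$counts["1999", "metal"], 2L, ignore_attr = TRUE)
  expect_equal(trend$counts["2001", "metal"], 1L, ignore_attr = TRUE)
  expect_equal(trend$counts["2001", "PCB"], 2L, ignore_attr = TRUE)
  expect_equal(trend$counts["2005", "PCB"], 1L, ignore_attr = TRUE)
  expect_equal(trend$counts["2005", "not characterized"], 1L,
               ignore_attr = TRUE)
  expect_equal(sum(trend$counts), total_counts(corp))
  # zero-membership class yields a zero column when labels are supplied
  tx2 <- class_taxonomy(list(chemical_list("metal", cs[1]),
                             chemical_list("empty", rand_casrns(1, 990000L))))
  prof2 <- assign_classes(build_profiles(corp), tx2)$profiles
  trend2 <- annual_class_counts(corp, prof2, labels = taxonomy_labels(tx2))
  expect_equal(sum(trend2$counts[, "empty"]), 0L)
})

test_that("share series sum to 100% over a partition; empty years are NA", {
  corp <- toy_corpus()
  prof <- build_profiles(corp)
  cs <- toy_casrns()
  tx <- class_taxonomy(list(chemical_list("metal", cs[1])))
  prof <- assign_classes(prof, tx)$profiles
  trend <- annual_class_counts(corp, prof)
  labels <- colnames(trend$counts)
  shares <- sapply(labels, function(l) share_series(trend, l)$share_pct)
  nonzero <- trend$totals_by_year > 0
  expect_equal(unname(rowSums(shares)[nonzero]),
               rep(100, sum(nonzero)))
  expect_true(all(is.na(shares[!nonzero, ])))   # undefined, not 0
  # single-class corpus -> 100% every reporting year
  solo <- corpus(tibble::tibble(record_id = c("x", "y"), year = c(2001L, 2002L),
                                roles = list("ANST", "ANST"),
                                casrns = list(cs[1], cs[1])))
  ptx <- assign_classes(build_profiles(solo), tx)$profiles
  st <- annual_class_counts(solo, ptx)
  expect_equal(share_series(st, "metal")$share_pct, c(100, 100))
  expect_error(share_series(trend, "nope"), "unknown class label")
})

test_that("top-N shares are deterministic, monotone, and end at 1", {
  cc <- concentration_curve(c(a = 5, b = 3, c = 2))
  expect_equal(top_n_share(cc, 2), 0.8)
  expect_equal(top_n_share(cc, 3), 1)
  expect_error(top_n_share(cc, 0))
  expect_error(top_n_share(cc, 4))
  set.seed(12)
  totals <- stats::setNames(rpois(200, 20), rand_casrns(200))
  curve <- concentration_curve(totals)
  shares <- vapply(seq_along(totals), function(n) top_n_share(curve, n),
                   numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[length(shares)], 1)
  # ties broken by canonical CASRN ascending
  tied <- concentration_curve(c(`50-00-0` = 2, `1746-01-6` = 2, `57-12-5` = 1))
  expect_equal(tied$casrn, c("1746-01-6", "50-00-0", "57-12-5"))
})

test_that("concentration statistics ignore record order", {
  set.seed(44)
  cfg <- synthetic_config(n_substances = 150, years = c(2000L, 2004L),
                          base_records_per_year = 30, seed = 3L)
  corp <- generate_corpus(cfg)$corpus
  prof1 <- build_profiles(corp)
  prof2 <- build_profiles(corpus(corp[sample.int(nrow(corp)), ]))
  c1 <- concentration_curve(prof1)
  c2 <- concentration_curve(prof2)
  expect_equal(c1$casrn, c2$casrn)
  expect_equal(c1$cum_share, c2$cum_share)
})

test_that("percent formatting rounds half-up with table-style precision", {
  expect_equal(format_percent(0.3402), "34%")
  expect_equal(format_percent(0.0078948), "0.79%")
  expect_equal(format_percent(0), "0%")
  expect_equal(format_percent(0.345, decimals = 0), "35%") # half-up, not half-even
  expect_equal(format_percent(0.00185, decimals = 2), "0.19%")
  expect_equal(format_percent(0.105), "11%")               # integer at >= 10%
  expect_equal(format_percent(0.0999), "10%")              # 9.99 -> 2 sig figs -> 10
  expect_equal(format_percent(0.011359), "1.1%")
  expect_equal(format_percent(c(0.5, NA)), c("50%", NA))
})

test_that("substance shares reproduce mixed table formatting", {
  expect_equal(substance_share(140527, 413007), "34%")
  expect_equal(substance_share(73043, 9251975), "0.79%")
  expect_equal(substance_share(743, 413007), "0.18%")
  expect_equal(substance_share(0, 413007), "0%")
})

test_that("newly-reported series conserves the unique substance count", {
  corp <- toy_corpus()
  prof <- build_profiles(corp)
  trend <- annual_class_counts(corp, prof)
  fy <- dedup_earliest(corp)
  nr <- newly_reported_series(fy, trend)
  expect_equal(sum(nr$n_new), length(unique(unlist(corp$casrns))))
  expect_equal(nr$n_new[nr$year == 1999], 1L)
  expect_equal(nr$n_new[nr$year == 2001], 1L)
  expect_equal(nr$n_new[nr$year == 2005], 1L)
  expect_true(all(nr$n_new[nr$year %in% c(2000, 2002:2004)] == 0L))
  # percentages use the year's total reports as denominator
  expect_equal(nr$pct_of_total[nr$year == 1999], 100 * 1 / 2)
  # all substances first seen in year one -> zeros afterwards
  cs <- toy_casrns()
  first <- corpus(tibble::tibble(
    record_id = c("a", "b"), year = c(2000L, 2003L),
    roles = list("ANST", "ANST"),
    casrns = list(cs, cs)))
  pf <- build_profiles(first)
  tr <- annual_class_counts(first, pf)
  nr2 <- newly_reported_series(dedup_earliest(first), tr)
  expect_equal(nr2$n_new, c(3L, 0L, 0L, 0L))
})
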
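test_that("earliest-year dedup keeps each substance's first report", {
  cs <- toy_casrns()
  corp <- toy_corpus()
  fy <- dedup_earliest(corp)
  expect_equal(fy$first_year[match(cs, fy$casrn)], c(1999L, 2001L, 2005L))
  # listed once each, ordered by (first_year, casrn)
  expect_equal(anyDuplicated(fy$casrn), 0L)
  expect_equal(fy, dplyr::arrange(fy, first_year, casrn))
})

test_that("dedup output is invariant to record order and idempotent", {
  corp <- toy_corpus()
  fy <- dedup_earliest(corp)
  set.seed(99)
  for (i in 1:5) {
    shuffled <- corpus(corp[sample.int(nrow(corp)), ])
    expect_equal(dedup_earliest(shuffled), fy)
  }
  # one-record-per-substance corpus built from the output maps to itself
  self <- corpus(tibble::tibble(
    record_id = fy$casrn, year = fy$first_year,
    roles = list("ANST"), casrns = as.list(fy$casrn)))
  expect_equal(dedup_earliest(self), fy)
})

test_that("profiles conserve counts and derive first years", {
  corp <- toy_corpus()
  prof <- build_profiles(corp)
  # brute-force tally oracle over the flat rows
  flat <- data.frame(casrn = unlist(corp$casrns),
                     year = rep(corp$year, lengths(corp$casrns)))
  oracle_totals <- table(flat$casrn)
  expect_equal(sum(prof$profiles$total_count), total_counts(corp))
  expect_equal(prof$profiles$total_count[match(names(oracle_totals),
                                               prof$profiles$casrn)],
               as.integer(oracle_totals), ignore_attr = TRUE)
  # counts_by_year complete over the year range, zeros included
  yr <- year_range(corp)
  expect_equal(sort(unique(prof$counts$year)), seq.int(yr[1], yr[2]))
  expect_equal(nrow(prof$counts),
               length(unique(flat$casrn)) * (yr[2] - yr[1] + 1L))
  per_sub <- tapply(prof$counts$count, prof$counts$casrn, sum)
  expect_equal(as.integer(per_sub[prof$profiles$casrn]),
               prof$profiles$total_count)
})

test_that("exclusion screening removes by first category, spares whitelist", {
  cs <- rand_casrns(10)
  prof <- as_profiles(tibble::tibble(casrn = cs))
  rs <- exclusion_ruleset(
    categories = list(minerals = cs[1:3], polymers = cs[3:5]),
    whitelist = cs[c(2, 9)]
  )
  res <- apply_exclusions(prof, rs)
  expect_equal(res$report$input_count,
               res$report$kept_count + res$report$removed_total)
  expect_equal(res$report$removed_total,
               sum(res$report$removed_by_category))
  # cs[2] whitelisted -> kept despite minerals membership
  expect_true(cs[2] %in% res$kept$profiles$casrn)
  # cs[3] in both categories -> counted once, under the earlier one
  expect_equal(res$removed$excluded_by[res$removed$casrn == cs[3]], "minerals")
  expect_equal(res$report$removed_by_category,
               c(minerals = 2L, polymers = 2L))
  # empty ruleset is the identity
  id <- apply_exclusions(prof, exclusion_ruleset())
  expect_equal(id$kept$profiles, prof$profiles)
  expect_equal(id$report$removed_total, 0L)
})

test_that("whitelist supremacy holds for arbitrary rulesets", {
  set.seed(5)
  cs <- rand_casrns(50)
  prof <- as_profiles(tibble::tibble(casrn = cs))
  for (i in 1:10) {
    cats <- list(a = sample(cs, 20), b = sample(cs, 20), c = sample(cs, 10))
    wl <- sample(cs, 8)
    res <- apply_exclusions(prof, exclusion_ruleset(cats, wl))
    expect_true(all(wl %in% res$kept$profiles$casrn))
    expect_equal(res$report$input_count,
                 res$report$kept_count + res$report$removed_total)
  }
})

test_that("food-constituent screen composes as one more category", {
  cs <- rand_casrns(6)
  prof <- as_profiles(tibble::tibble(casrn = cs))
  food <- chemical_list("FooDB-like (synthetic)", c(cs[1], rand_casrns(2, 900000L)))
  res <- food_constituent_screen(prof, food)
  expect_equal(res$removed$casrn, cs[1])
  expect_match(res$removed$excluded_by, "FooDB")
  # on the whitelist -> kept
  res_wl <- food_constituent_screen(prof, food, whitelist = cs[1])
  expect_equal(nrow(res_wl$removed), 0L)
  # disjoint list -> identity
  disjoint <- chemical_list("food", rand_casrns(3, 800000L))
  expect_equal(food_constituent_screen(prof, disjoint)$kept$profiles,
               prof$profiles)
})

test_that("exclusion rules read from category files and combined files agree", {
  cs <- rand_casrns(8)
  d <- withr::local_tempdir()
  writeLines(c("casrn", cs[1:3]), file.path(d, "minerals.tsv"))
  writeLines(c("casrn", cs[3:4]), file.path(d, "polymers.tsv"))
  writeLines(c("casrn", cs[2]), file.path(d, "whitelist.tsv"))
  rs1 <- read_exclusion_rules(file.path(d, c("minerals.tsv", "polymers.tsv")),
                              file.path(d, "whitelist.tsv"))
  combined <- file.path(d, "combined.tsv")
  writeLines(c("casrn\tcategory",
               paste(cs[1:3], "minerals", sep = "\t"),
               paste(cs[3:4], "polymers", sep = "\t")), combined)
  rs2 <- read_exclusion_rules(combined, file.path(d, "whitelist.tsv"))
  expect_equal(rs1$categories, rs2$categories)
  expect_equal(rs1$whitelist, rs2$whitelist)
})
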
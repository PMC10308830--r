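test_that("classification follows precedence, CEC fallback, then label", {
  pool <- rand_casrns(40)
  tx <- toy_taxonomy(pool)
  prof <- as_profiles(tibble::tibble(casrn = pool[c(1, 9, 22, 26, 35)]))
  res <- assign_classes(prof, tx)
  labels <- res$profiles$profiles$class_label
  expect_equal(labels[1], "pharmaceutical")       # only on pharma list
  expect_equal(labels[2], "pharmaceutical")       # pharma beats pesticide
  expect_equal(labels[3], "PCB")
  expect_equal(labels[4], "CEC-only")             # only on the CEC list
  expect_equal(labels[5], "not characterized")    # on no list
  expect_equal(sum(res$summary$n), 5L)
  expect_equal(attr(res$summary, "cec_only_count"), 1L)
  expect_equal(attr(res$summary, "uncharacterized_count"), 1L)
})

test_that("classification partitions the input and ignores row order", {
  set.seed(31)
  pool <- rand_casrns(60)
  tx <- toy_taxonomy(pool)
  prof <- as_profiles(tibble::tibble(casrn = sample(pool, 45)))
  res <- assign_classes(prof, tx)
  expect_equal(sum(res$summary$n), nrow(prof$profiles))
  shuffled <- as_profiles(prof$profiles[sample.int(45), ])
  res2 <- assign_classes(shuffled, tx)
  j1 <- res$profiles$profiles[order(res$profiles$profiles$casrn),
                              c("casrn", "class_label")]
  j2 <- res2$profiles$profiles[order(res2$profiles$profiles$casrn),
                               c("casrn", "class_label")]
  expect_equal(j1, j2, ignore_attr = TRUE)
})

test_that("raising a list's precedence never shrinks its class", {
  set.seed(77)
  pool <- rand_casrns(50)
  prof <- as_profiles(tibble::tibble(casrn = pool))
  for (i in 1:8) {
    a <- sample(pool, 20); b <- sample(pool, 20)
    low <- class_taxonomy(list(chemical_list("A", a, precedence = 2L),
                               chemical_list("B", b, precedence = 1L)))
    high <- class_taxonomy(list(chemical_list("A", a, precedence = 1L),
                                chemical_list("B", b, precedence = 2L)))
    n_low <- assign_classes(prof, low)$summary
    n_high <- assign_classes(prof, high)$summary
    expect_gte(n_high$n[n_high$class_label == "A"],
               n_low$n[n_low$class_label == "A"])
  }
})

test_that("transformation products inherit the parent class unless listed", {
  pool <- rand_casrns(40)
  tx <- toy_taxonomy(pool)
  prof <- as_profiles(tibble::tibble(casrn = pool[c(1, 35, 36)]))
  res <- assign_classes(prof, tx)
  tp_map <- tibble::tibble(
    parent_casrn = pool[c(21, 21, 2)],
    tp_casrn = pool[c(35, 1, 36)],
    class = c("PCB", "PCB", "nosuch")
  )
  expect_warning(
    out <- annotate_transformation_products(res$profiles, tp_map, tx),
    "unknown class"
  )
  labels <- out$profiles$class_label
  expect_equal(labels[out$profiles$casrn == pool[35]], "PCB")   # hydroxy-PCB style TP
  expect_true(out$profiles$tp_flag[out$profiles$casrn == pool[35]])
  expect_equal(labels[out$profiles$casrn == pool[1]], "pharmaceutical") # list wins
  expect_false(out$profiles$tp_flag[out$profiles$casrn == pool[1]])
  expect_equal(labels[out$profiles$casrn == pool[36]], "not characterized")
  # empty map is the identity
  empty <- tibble::tibble(parent_casrn = character(), tp_casrn = character(),
                          class = character())
  expect_equal(annotate_transformation_products(res$profiles, empty, tx),
               res$profiles)
})

test_that("cross-list dedupe keeps the highest-precedence copy", {
  pool <- rand_casrns(30)
  tx <- class_taxonomy(list(
    chemical_list("bisphenols", pool[1:6], precedence = 1L),
    chemical_list("plastics additives", pool[4:12], precedence = 2L),
    chemical_list("fragrances", pool[c(6, 11:15)], precedence = 3L)
  ))
  res <- dedupe_lists(tx)
  members <- lapply(res$taxonomy$lists, `[[`, "members")
  all_pairs <- utils::combn(length(members), 2, function(ij) {
    length(intersect(members[[ij[1]]], members[[ij[2]]]))
  })
  expect_true(all(all_pairs == 0))
  # brute-force collision count over the original list pairs
  orig <- lapply(tx$lists, `[[`, "members")
  seen <- character()
  expected <- 0L
  for (m in orig) {
    expected <- expected + sum(m %in% seen)
    seen <- union(seen, m)
  }
  expect_equal(nrow(res$collisions), expected)
  expect_true(all(pool[4:6] %in% res$taxonomy$lists[["bisphenols"]]$members))
  expect_false(any(pool[4:6] %in% res$taxonomy$lists[["plastics additives"]]$members))
  # already-disjoint taxonomy is untouched
  disj <- class_taxonomy(list(chemical_list("a", pool[1:3]),
                              chemical_list("b", pool[4:6])))
  res2 <- dedupe_lists(disj)
  expect_equal(lapply(res2$taxonomy$lists, `[[`, "members"),
               lapply(disj$lists, `[[`, "members"))
  expect_equal(nrow(res2$collisions), 0L)
})

test_that("taxonomy config files load with precedence and CEC role", {
  d <- withr::local_tempdir()
  pool <- rand_casrns(20)
  writeLines(c("casrn", pool[1:5]), file.path(d, "pharma.tsv"))
  writeLines(c("casrn", pool[6:10]), file.path(d, "pcb.tsv"))
  writeLines(c("casrn", pool[11:18]), file.path(d, "cec.tsv"))
  writeLines(c("label\tpath\tprecedence\trole",
               "pharmaceutical\tpharma.tsv\t1\t",
               "PCB\tpcb.tsv\t2\t",
               "CEC\tcec.tsv\t99\tcec"),
             file.path(d, "taxonomy.tsv"))
  tx <- read_taxonomy(file.path(d, "taxonomy.tsv"))
  expect_equal(names(tx$lists), c("pharmaceutical", "PCB"))
  expect_equal(tx$cec_list$members, pool[11:18])
  expect_equal(taxonomy_labels(tx),
               c("pharmaceutical", "PCB", "CEC-only", "not characterized"))
})
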
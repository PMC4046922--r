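# Decision-table haplogroup classification, consistency checking,
# frequency tabulation and bootstrap intervals.

test_that("the default decision table loads with the expected rules", {
  tab <- load_decision_table()
  labels <- vapply(tab$rules, `[[`, "", "label")
  expect_setequal(labels, c("H", "HV", "HV0", "R0", "K", "U*", "N*", "L3"))
})

test_that("malformed decision tables are rejected", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("label\tsnp_conditions", "H\t7028C"), bad)
  expect_error(load_decision_table(bad), "lacks column")

  writeLines(c("label\tsnp_conditions\tmotif_conditions\tpriority",
               "H\t7028X\t.\t1"), bad)
  expect_error(load_decision_table(bad), "malformed condition")

  writeLines(c("label\tsnp_conditions\tmotif_conditions\tpriority",
               "H\t.\t.\t1"), bad)
  expect_error(load_decision_table(bad), "no conditions")

  writeLines(c("label\tsnp_conditions\tmotif_conditions\tpriority",
               "H\t7028C\t.\t1", "H\t7028C\t.\t2"), bad)
  expect_error(load_decision_table(bad), "duplicate")
})

test_that("classification reproduces the fixture's published labels", {
  calls <- classify_ppnb_fixture()
  fx <- ppnb_fixture()
  expect_equal(calls$label, fx$profiles$haplogroup)
  expect_equal(sum(calls$firm), 14L)
  expect_false(calls$firm[calls$sample_id == "H53"])
})

test_that("single profiles classify as published", {
  tab <- load_decision_table()
  # K: U-defining 12308G with 10550G, motif 16311C
  k <- classify_profile(parse_motif("16311C"),
                        data.frame(position = c(7028, 12308, 10550),
                                   base = c("T", "G", "G"),
                                   validated = TRUE), tab)
  expect_equal(k$label, "K")
  expect_true(k$firm)

  # H: rCRS allele at 7028
  h <- classify_profile(parse_motif("16294T", window = c(16256L, 16369L)),
                        data.frame(position = 7028, base = "C",
                                   validated = TRUE), tab)
  expect_equal(h$label, "H")

  # nothing to go on
  u <- classify_profile(parse_motif("CRS"), NULL, tab)
  expect_true(is.na(u$label))
  expect_false(u$firm)
})

test_that("classification is deterministic and order-independent", {
  tab <- load_decision_table()
  snps <- data.frame(position = c(10550, 12308, 7028),
                     base = c("G", "G", "T"), validated = TRUE)
  a <- classify_profile(parse_motif("16311C 16224C"), snps, tab)
  b <- classify_profile(parse_motif("16224C 16311C"),
                        snps[c(3, 1, 2), ], tab)
  expect_equal(a$label, b$label)
})

test_that("overriding one rule changes only that label's calls", {
  fx <- ppnb_fixture()
  base_calls <- classify_ppnb_fixture()
  # rewrite the U* rule to an inert condition set
  tab <- utils::read.delim(system.file("extdata", "decision_table.tsv",
                                       package = "paleomito"),
                           stringsAsFactors = FALSE,
                           na.strings = character(0))
  tab$snp_conditions[tab$label == "U*"] <- "12308G;10550A;4646C"
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(tab, tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  new_calls <- classify_ppnb_fixture(load_decision_table(tmp))
  changed <- new_calls$label != base_calls$label
  expect_true(all(base_calls$label[changed] == "U*"))
})

test_that("consistency checking compares motif and SNP candidate sets", {
  tab <- load_decision_table()
  h <- parse_motif("16224C 16311C")
  snps <- data.frame(position = c(12308, 10550), base = c("G", "G"),
                     validated = TRUE)
  call <- classify_profile(h, snps, tab)
  expect_equal(consistency_check(h, snps, call, tab)$consistency,
               "consistent")

  # H-defining SNP with an L3-only motif: disjoint candidates
  h2 <- parse_motif("16223T")
  snps2 <- data.frame(position = 7028, base = "C", validated = TRUE)
  call2 <- classify_profile(h2, snps2, tab)
  expect_equal(consistency_check(h2, snps2, call2, tab)$consistency,
               "conflict")

  # motif-only profile: untestable
  call3 <- classify_profile(h, NULL, tab)
  expect_equal(consistency_check(h, NULL, call3, tab)$consistency,
               "untestable")
})

test_that("frequencies sum to 100 over firm calls and reject unmapped labels", {
  calls <- classify_ppnb_fixture()
  freq <- haplogroup_frequencies(calls$label, firm = calls$firm,
                                 grouping = NULL)
  expect_equal(sum(freq$pct), 100, tolerance = 1e-9)
  expect_equal(freq$pct[freq$category == "K"], 100 * 6 / 14)

  one <- haplogroup_frequencies("K", grouping = NULL)
  expect_equal(one$pct, 100)

  expect_error(haplogroup_frequencies(c("K", "ZZZ")), "ZZZ")

  # random multisets against a counting oracle
  set.seed(111)
  cats <- c("K", "H", "R0", "T", "J")
  for (i in seq_len(20)) {
    labs <- sample(cats, sample(5:40, 1), replace = TRUE)
    freq <- haplogroup_frequencies(labs, grouping = NULL)
    for (cc in unique(labs)) {
      expect_equal(freq$n[freq$category == cc], sum(labs == cc))
    }
    expect_equal(sum(freq$pct), 100, tolerance = 1e-9)
  }
})

test_that("pooling maps raw labels onto the 25 categories", {
  g <- load_grouping_scheme()
  expect_equal(unname(g[c("L3", "M1", "B", "U8", "R1", "V")]),
               c("AF", "AF", "AS", "U+", "R+", "HV0"))
  freq <- haplogroup_frequencies(c("L3", "L2", "K"), grouping = g)
  expect_equal(freq$n[freq$category == "AF"], 2L)
})

test_that("bootstrap intervals behave at the boundaries and match binomial quantiles", {
  # absent category never appears in resamples
  ci <- bootstrap_ci(c("K", "K", "H"), B = 200, seed = 1)
  expect_true(all(ci$lower <= ci$pct & ci$pct <= ci$upper))

  ci1 <- bootstrap_ci(rep("K", 5), B = 200, seed = 1)
  expect_equal(ci1$lower, 100)
  expect_equal(ci1$upper, 100)

  expect_error(bootstrap_ci(character(0), B = 200, seed = 1), "empty")
  expect_error(bootstrap_ci("K", B = 200), "seed")

  # n = 14, p = 6/14: percentile CI vs exact binomial quantiles (the
  # resample count is exactly Binomial(14, 6/14); the band accounts for
  # Monte-Carlo error at CDF steps)
  labels <- c(rep("K", 6), rep("other", 8))
  ci <- bootstrap_ci(labels, B = 10000, seed = 99)
  k_row <- ci[ci$category == "K", ]
  lo_band <- binom_quantile_band(0.025, 14, 6 / 14, 10000)
  hi_band <- binom_quantile_band(0.975, 14, 6 / 14, 10000)
  expect_gte(k_row$lower, lo_band[1] - 2)
  expect_lte(k_row$lower, lo_band[2] + 2)
  expect_gte(k_row$upper, hi_band[1] - 2)
  expect_lte(k_row$upper, hi_band[2] + 2)

  # reproducibility
  expect_identical(bootstrap_ci(labels, B = 300, seed = 7),
                   bootstrap_ci(labels, B = 300, seed = 7))
})
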
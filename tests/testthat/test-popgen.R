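# Shared haplotypes, pairwise FST with permutation significance, BH
# adjustment and population pooling.

test_that("FST equals the brute-force AMOVA oracle on random instances", {
  set.seed(121)
  haps <- paste0("h", 1:5)
  for (i in seq_len(200)) {
    a <- sample(haps, sample(2:12, 1), replace = TRUE)
    b <- sample(haps, sample(2:12, 1), replace = TRUE)
    expect_equal(pairwise_fst(a, b), amova_fst_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(pairwise_fst(a, b), pairwise_fst(b, a))   # symmetry
  }
})

test_that("FST boundary cases behave as defined", {
  expect_equal(pairwise_fst(rep("X", 4), rep("Y", 4)), 1)
  expect_equal(pairwise_fst(rep("X", 5), rep("X", 7)), 0)
  expect_error(pairwise_fst("X", c("X", "Y")), ">= 2")
  # same composition: the estimate is 0 up to the O(1/n) small-sample bias
  a <- rep(c("h1", "h2", "h3"), times = c(40, 30, 30))
  expect_lt(abs(pairwise_fst(a, a)), 0.02)
})

test_that("permutation p-values are reproducible and hit the lower bound", {
  a <- rep("X", 6); b <- rep("Y", 6)
  r <- fst_permutation_test(a, b, n_perm = 999, seed = 5)
  # no permutation can exceed complete fixation... but ties count, so the
  # add-one minimum is attained only when no permuted value reaches 1
  expect_lte(r$p_raw, (1 + sum(choose(6, 0))) / 1000 + 0.01)
  expect_identical(r,
                   fst_permutation_test(a, b, n_perm = 999, seed = 5))
  expect_error(fst_permutation_test(a, b, n_perm = 999), "seed")
})

test_that("permutation p is uniform under the null", {
  # population-scale samples with moderate haplotype diversity: the
  # permutation distribution of FST is rich enough that ties (counted as
  # exceedances) stay negligible
  pool_haps <- paste0("h", 1:12)
  pvals <- vapply(seq_len(1000), function(i) {
    set.seed(20000 + i)
    x <- sample(pool_haps, 120, replace = TRUE)
    fst_permutation_test(x[1:60], x[61:120], n_perm = 199,
                         seed = 7000 + i)$p_raw
  }, 0)
  # type-I error at alpha = 0.05 within its binomial 95% CI
  rej <- mean(pvals <= 0.05)
  expect_gt(rej, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 1000))
  # Kolmogorov-Smirnov against uniform, alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand-computed staircase: p_(i) * m / i, cumulative minimum from above:
  # sorted (0.005, 0.03, 0.04, 0.8) -> (0.02, 0.06, 0.0533, 0.8) -> min
  # from the top -> (0.02, 0.0533, 0.0533, 0.8)
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.04 * 4 / 3, 0.04 * 4 / 3, 0.8))
  set.seed(141)
  for (i in seq_len(20)) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone in the order of the sorted raw p-values
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("population pooling concatenates members and rejects unmapped", {
  db <- data.frame(individual_id = sprintf("i%d", 1:10),
                   population = rep(c("p1", "p2"), each = 5),
                   motif = "CRS", haplogroup = "H")
  pooled <- pool_populations(db, c(p1 = "west", p2 = "west"))
  expect_equal(nrow(pooled), 10L)
  expect_equal(unique(pooled$population), "west")
  expect_error(pool_populations(db, c(p1 = "west")), "unmapped")
  excl <- pool_populations(db, c(p1 = "west", p2 = "exclude"))
  expect_equal(nrow(excl), 5L)
})

test_that("pooling preserves carrier counts for any query haplotype", {
  set.seed(151)
  db <- data.frame(individual_id = sprintf("i%d", 1:60),
                   population = rep(c("p1", "p2", "p3"), each = 20),
                   motif = sample(c("16224C 16311C", "16311C", "CRS"),
                                  60, replace = TRUE),
                   haplogroup = "K")
  query <- data.frame(motif = "16224C 16311C", window_lo = 16126L,
                      window_hi = 16369L, haplogroup = "K")
  before <- shared_haplotypes(query, db)
  pooled <- pool_populations(db, c(p1 = "all", p2 = "all", p3 = "all"))
  after <- shared_haplotypes(query, pooled)
  expect_equal(sum(before$n_carriers), after$n_carriers)
  expect_equal(after$n_individuals, 60L)
})

test_that("shared-haplotype counts match an exhaustive-scan oracle", {
  fx <- ppnb_fixture()
  # query against itself: everything shared, everyone a carrier
  complete <- fx$profiles[fx$profiles$window_lo == 16126 &
                            fx$profiles$window_hi == 16369, ]
  self_db <- data.frame(individual_id = complete$sample_id,
                        population = "PPNB", motif = complete$motif,
                        haplogroup = complete$haplogroup)
  res <- shared_haplotypes(fx$profiles, self_db)
  expect_equal(res$pct_carriers, 100)
  expect_equal(res$pct_shared_haplotypes, 100)

  # toy database with three planted matches
  db <- data.frame(
    individual_id = sprintf("i%d", 1:10),
    population = "toy",
    motif = c("16224C 16311C", "16224C 16311C", "16311C", "CRS",
              "16234T", "16256T", "16293C", "16319A", "16356C 16362C",
              "16224C 16311C 16366T"),
    haplogroup = c("K", "K", "K", "H", "H", "H", "R0", "U*", "N*", "K"))
  res <- shared_haplotypes(fx$profiles, db, require_haplogroup = TRUE)
  # oracle: exhaustive scan over distinct complete query motifs
  qs <- unique(complete[c("motif", "haplogroup")])
  hit <- vapply(seq_len(nrow(db)), function(i) {
    any(db$motif[i] == qs$motif & db$haplogroup[i] == qs$haplogroup)
  }, TRUE)
  expect_equal(res$n_carriers, sum(hit))
  expect_equal(res$n_shared_haplotypes,
               length(unique(db$motif[hit])))

  # haplogroup agreement is enforced when required
  db2 <- db; db2$haplogroup[1:2] <- "U5"
  res2 <- shared_haplotypes(fx$profiles, db2, require_haplogroup = TRUE)
  res3 <- shared_haplotypes(fx$profiles, db2, require_haplogroup = FALSE)
  expect_equal(res2$n_carriers, res$n_carriers - 2L)
  expect_equal(res3$n_carriers, res$n_carriers)

  expect_error(shared_haplotypes(fx$profiles[0, ], db), "empty")
})

test_that("FST increases with planted divergence", {
  set.seed(161)
  founders_a <- paste0("a", 1:4); founders_b <- paste0("b", 1:4)
  fst_at <- vapply(c(0, 0.25, 0.5, 1), function(q) {
    # population B draws a fraction q of its individuals from a disjoint
    # founder set
    mean(vapply(1:20, function(i) {
      a <- sample(founders_a, 40, replace = TRUE)
      from_b <- runif(40) < q
      b <- ifelse(from_b, sample(founders_b, 40, replace = TRUE),
                  sample(founders_a, 40, replace = TRUE))
      pairwise_fst(a, b)
    }, 0))
  }, 0)
  expect_true(all(diff(fst_at) > 0))
})

test_that("fst_scan adjusts one family of p-values and is seeded", {
  set.seed(171)
  db <- data.frame(individual_id = sprintf("i%d", 1:60),
                   population = rep(c("p1", "p2", "p3"), each = 20),
                   motif = sample(c("16224C 16311C", "16311C", "CRS",
                                    "16234T"), 60, replace = TRUE),
                   haplogroup = NA)
  q <- rep(c("16224C 16311C", "CRS"), each = 5)
  r1 <- fst_scan(q, db, n_perm = 199, seed = 3)
  r2 <- fst_scan(q, db, n_perm = 199, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$p_adjusted, bh_adjust(r1$p_raw))
})
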
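# Clone-origin labelling and reproducibility-validated consensus calling.

test_that("per-amplicon consensus takes the per-position majority", {
  cs <- make_amplicon(rep("16311C", 10), fragment = 2L)
  out <- per_amplicon_consensus(cs, test_ref)
  expect_equal(format_motif(out$haplotype), "16311C")
  expect_equal(out$support$n_support, 10L)
  expect_equal(out$support$n_clones, 10L)

  cs <- make_amplicon(c(rep("16311C", 9), "CRS"), fragment = 2L)
  out <- per_amplicon_consensus(cs, test_ref)
  expect_equal(format_motif(out$haplotype), "16311C")
  expect_equal(out$support$n_support, 9L)
})

test_that("majority ties resolve to the reference and are flagged", {
  cs <- make_amplicon(c(rep("16311C", 5), rep("CRS", 5)), fragment = 2L)
  out <- per_amplicon_consensus(cs, test_ref)
  expect_equal(format_motif(out$haplotype), "CRS")
  expect_equal(out$ambiguous_positions, 16311L)
})

test_that("consensus matches a per-position counting oracle", {
  set.seed(606)
  scored <- fragment_scored_positions(1L, test_ref)
  for (rep in seq_len(25)) {
    n <- sample(5:15, 1)
    motifs <- replicate(n, {
      k <- sample(0:3, 1)
      if (k == 0) "CRS" else {
        pos <- sort(sample(scored, k))
        paste0(pos, sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = " ")
      }
    })
    cs <- make_amplicon(motifs)
    out <- per_amplicon_consensus(cs, test_ref)
    # oracle: tabulate states clone by clone at every scored position
    haps <- lapply(motifs, parse_motif,
                   window = c(16126L, 16258L))
    for (p in scored) {
      states <- vapply(haps, function(h) {
        i <- match(p, h$positions)
        if (is.na(i)) ref_base(test_ref, p) else h$bases[i]
      }, "")
      tab <- table(states)
      top <- names(tab)[tab == max(tab)]
      expected <- if (length(top) > 1) {
        rb <- ref_base(test_ref, p)
        if (rb %in% top) rb else sort(top)[1]
      } else top
      got <- out$support$base[match(p, out$support$position)]
      if (expected == ref_base(test_ref, p)) {
        expect_true(is.na(got) || !(p %in% out$haplotype$positions))
      } else {
        expect_equal(got, expected)
      }
    }
  }
})

test_that("clone-origin labelling separates staff, carry-over and damage", {
  staff <- data.frame(person_id = "staff01", motif = "16224C 16256T")
  neighbors <- data.frame(sample_id = "S2", motif = "16234T")

  cs <- make_amplicon(rep("16311C", 8), fragment = 2L)
  lab <- label_clone_origins(cs, staff, neighbors, test_ref)
  expect_true(all(lab$origin == "endogenous"))

  # fragment 1 amplicon: majority CRS, one staff clone, one carry-over,
  # one damaged clone (type 2: C->T at 16234, ref C), one chimera-like
  cs <- make_amplicon(c(rep("CRS", 7), "16224C 16256T", "16234T",
                        "16145C"))
  lab <- label_clone_origins(cs, staff, neighbors, test_ref)
  expect_equal(lab$origin[8], "staff_contaminant")
  expect_equal(lab$origin[9], "carry_over")
  # 16145 ref G; G->C is neither lesion type
  expect_equal(lab$origin[10], "unclassified")

  # a clone differing from the majority only by lesion-typed changes is
  # damage on the endogenous template
  cs <- make_amplicon(c(rep("16311C", 7), "16290T 16311C"), fragment = 2L)
  lab <- label_clone_origins(cs, staff = staff, ref = test_ref)
  expect_equal(lab$origin[8], "endogenous")   # 16290 ref C, C->T type 2
})

test_that("empty staff panel skips the check with a warning", {
  cs <- make_amplicon(rep("CRS", 5))
  expect_warning(label_clone_origins(cs, staff = NULL, ref = test_ref),
                 "staff")
  expect_error(label_clone_origins(cs[0, ], ref = test_ref), "empty")
})

test_that("planted carry-over clones are recovered on damage-free data", {
  set.seed(707)
  staff <- data.frame(person_id = "staff01", motif = "16129A 16209C")
  hits <- 0L; planted <- 0L; false_pos <- 0L; n_endo <- 0L
  for (rep in seq_len(20)) {
    truth <- "16224C"
    neighbor <- "16234T 16256T"
    n <- 12L
    carry <- sample(n, 2)
    motifs <- rep(format_motif(trim_to_window(parse_motif(truth),
                                              c(16126L, 16258L))), n)
    motifs[carry] <- format_motif(trim_to_window(parse_motif(neighbor),
                                                 c(16126L, 16258L)))
    cs <- make_amplicon(motifs)
    lab <- label_clone_origins(cs, staff,
                               data.frame(sample_id = "S9",
                                          motif = neighbor), test_ref)
    hits <- hits + sum(lab$origin[carry] == "carry_over")
    planted <- planted + length(carry)
    false_pos <- false_pos + sum(lab$origin[-carry] == "carry_over")
    n_endo <- n_endo + (n - length(carry))
  }
  expect_gte(hits / planted, 0.95)
  expect_equal(false_pos, 0L)
})

test_that("variants require attestation in two independent extractions", {
  # both extracts agree: validated profile with the shared variant
  cs <- rbind(
    make_amplicon(rep("16311C", 10), extraction = "E1", fragment = 2L),
    make_amplicon(rep("16311C", 10), extraction = "E2", fragment = 2L))
  cs$origin <- "endogenous"
  prof <- call_sample_consensus(cs, ref = test_ref)
  expect_equal(prof$status, "validated")
  expect_equal(format_motif(prof$haplotype), "16311C")
  expect_equal(prof$haplotype$window, c(16258L, 16369L))

  # a variant seen in only one extract is excluded and logged
  cs <- rbind(
    make_amplicon(rep("16311C 16319A", 10), extraction = "E1",
                  fragment = 2L),
    make_amplicon(rep("16311C", 10), extraction = "E2", fragment = 2L))
  cs$origin <- "endogenous"
  prof <- call_sample_consensus(cs, ref = test_ref)
  expect_equal(format_motif(prof$haplotype), "16311C")
  expect_equal(prof$dropped$position, 16319L)

  # single extraction: independent PCRs are accepted as the fallback
  cs <- rbind(
    make_amplicon(rep("16311C", 10), extraction = "E1", pcr = "P1",
                  fragment = 2L),
    make_amplicon(rep("16311C", 10), extraction = "E1", pcr = "P2",
                  fragment = 2L))
  cs$origin <- "endogenous"
  prof <- call_sample_consensus(cs, ref = test_ref)
  expect_equal(prof$status, "validated")
  expect_equal(format_motif(prof$haplotype), "16311C")

  # one amplification only: nothing replicates, profile discarded
  cs <- make_amplicon(rep("16311C", 10), fragment = 2L)
  cs$origin <- "endogenous"
  prof <- call_sample_consensus(cs, ref = test_ref)
  expect_equal(prof$status, "discarded")
})

test_that("SNP typings validate only when replicated across extracts", {
  cs <- rbind(
    make_amplicon(rep("CRS", 10), extraction = "E1"),
    make_amplicon(rep("CRS", 10), extraction = "E2"))
  cs$origin <- "endogenous"
  snps <- data.frame(position = c(7028L, 7028L, 12308L),
                     base = c("T", "T", "G"),
                     extraction_id = c("E1", "E2", "E1"))
  prof <- call_sample_consensus(cs, snp_typings = snps, ref = test_ref)
  expect_equal(prof$snp_typings$validated[
    prof$snp_typings$position == 7028], TRUE)
  expect_equal(prof$snp_typings$validated[
    prof$snp_typings$position == 12308], FALSE)
})

test_that("undamaged, uncontaminated experiments recover truth exactly", {
  cfg <- simulation_config(lambda = 0, contaminant_fraction = 0,
                           carryover_fraction = 0, seed = 11L)
  staff <- simulate_staff_panel(3, cfg)
  set.seed(808)
  for (i in seq_len(10)) {
    truth <- random_true_motif(sample(0:3, 1))
    exp <- simulate_clone_experiment(truth, cfg, staff = staff,
                                     sample_id = paste0("S", i),
                                     seed = 900 + i)
    prof <- consensus_from_clones(exp$clones, staff = staff)
    expect_equal(prof$status, "validated")
    expect_true(same_motif(prof$haplotype,
                           parse_motif(truth)))
  }
})
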
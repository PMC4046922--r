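# Shared test helpers: independent oracles and small generators.

# Random canonical motif string over the HVS1 window (no deletions unless
# asked).  Positions are distinct and sorted; bases differ from nothing in
# particular (motif grammar does not require a reference).
random_motif_string <- function(n_var = sample(0:4, 1),
                                window = hvs1_window(),
                                deletions = FALSE) {
  if (n_var == 0) return("CRS")
  pos <- sort(sample(seq(window[1], window[2]), n_var))
  states <- if (deletions) c("A", "C", "G", "T", "d") else
    c("A", "C", "G", "T")
  paste0(pos, sample(states, n_var, replace = TRUE), collapse = " ")
}

# Random biologically valid motif: derived base differs from the
# reference and positions avoid the poly-C exclusion (such motifs survive
# sequence round trips and clone simulation unchanged).
random_true_motif <- function(n_var = sample(0:3, 1),
                              ref = synthetic_hvs1_reference(),
                              window = hvs1_window()) {
  if (n_var == 0) return("CRS")
  pool <- setdiff(seq(window[1], window[2]), excluded_positions(ref))
  pos <- sort(sample(pool, n_var))
  bases <- vapply(ref_base(ref, pos), function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste0(pos, bases, collapse = " ")
}

# Brute-force AMOVA FST oracle: enumerates the full pairwise identity
# distance matrix and decomposes sums of squares directly.
amova_fst_oracle <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a); nb <- length(b)
  d <- outer(x, x, FUN = function(p, q) as.numeric(p != q))
  ssd_t <- sum(d[upper.tri(d)]) / n
  da <- d[seq_len(na), seq_len(na), drop = FALSE]
  db <- d[na + seq_len(nb), na + seq_len(nb), drop = FALSE]
  ssd_w <- sum(da[upper.tri(da)]) / na + sum(db[upper.tri(db)]) / nb
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a
  ms_w <- ssd_w / (n - 2)
  n_prime <- n - (na^2 + nb^2) / n
  s_a <- (ms_a - ms_w) / n_prime
  s_w <- ms_w
  if (s_a + s_w == 0) 0 else s_a / (s_a + s_w)
}

# Build a clone table for one amplicon from motif strings.
make_amplicon <- function(motifs, sample_id = "S1", extraction = "E1",
                          pcr = "P1", fragment = 1L, batch = "B1",
                          origin = "unclassified") {
  data.frame(clone_id = sprintf("%s-%s-%s-F%d-C%02d", sample_id,
                                extraction, pcr, fragment,
                                seq_along(motifs)),
             sample_id = sample_id, extraction_id = extraction,
             pcr_id = pcr, fragment_id = fragment, batch_id = batch,
             motif = motifs, origin = origin)
}

# Exact binomial quantile band for a bootstrap percentile: because the
# bootstrap count distribution is a lattice, a quantile whose target
# probability falls within Monte-Carlo error of a CDF step can land on
# either neighbouring support point; the band brackets both.
binom_quantile_band <- function(prob, n, p, B) {
  se <- sqrt(prob * (1 - prob) / B)
  100 * qbinom(c(max(prob - 3 * se, 0), min(prob + 3 * se, 1)), n, p) / n
}

test_ref <- synthetic_hvs1_reference()
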
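# Multi-population comparison: shared-haplotype statistics and pairwise
# FST from haplotype identity with permutation significance.
#
# FST follows the two-population AMOVA with inter-haplotype distance 0 for
# identical variant sets and 1 otherwise (the conventional "pairwise FST
# from haplotype frequencies"): variance components are derived from sums
# of squared differences among and within populations and the fixation
# index is sigma2_a / (sigma2_a + sigma2_w).  Negative estimates are
# reported as computed.

#' Shared-haplotype statistics against a database
#'
#' For every population of the database, counts (a) how many of the
#' query's distinct haplotypes occur in that population and (b) how many
#' of the population's individuals carry a query haplotype.  Haplotype
#' identity means equal variant sets over the comparison window;
#' haplogroup affiliation is also required when `require_haplogroup` is
#' set and both sides carry a label.
#'
#' @param query Data frame of query profiles with columns `motif`,
#'   `window_lo`, `window_hi` and optionally `haplogroup` (the packaged
#'   fixture's `profiles` table has this shape).
#' @param db Haplotype database: data frame with columns `individual_id`,
#'   `population`, `motif`, `haplogroup`.
#' @param window Comparison window, default the complete HVS1 window.
#' @param require_haplogroup Require haplogroup agreement in addition to
#'   motif identity (default `TRUE`).
#' @param complete_only Use only query profiles whose covered window spans
#'   the whole comparison window (default `TRUE`).
#' @return Data frame per population: `population`, `n_individuals`,
#'   `n_shared_haplotypes`, `pct_shared_haplotypes`, `n_carriers`,
#'   `pct_carriers`.
#' @export
shared_haplotypes <- function(query, db, window = hvs1_window(),
                              require_haplogroup = TRUE,
                              complete_only = TRUE) {
  stopifnot(is.data.frame(query), is.data.frame(db),
            all(c("motif", "window_lo", "window_hi") %in% names(query)),
            all(c("individual_id", "population", "motif", "haplogroup")
                %in% names(db)))
  if (!nrow(query)) stop("empty query population")
  if (complete_only) {
    query <- query[query$window_lo <= window[1] &
                     query$window_hi >= window[2], , drop = FALSE]
    if (!nrow(query)) stop("no query profile covers the complete window")
  }
  qkey <- vapply(seq_len(nrow(query)), function(i) {
    h <- parse_motif(query$motif[i],
                     window = c(query$window_lo[i], query$window_hi[i]))
    motif_key(h, window)
  }, "")
  qhg <- if ("haplogroup" %in% names(query)) query$haplogroup else
    rep(NA_character_, nrow(query))
  qid <- if (require_haplogroup) paste(qkey, qhg) else qkey
  distinct <- !duplicated(qid)
  qkey <- qkey[distinct]; qhg <- qhg[distinct]
  dkey <- vapply(db$motif, function(m) {
    motif_key(parse_motif(m, window = hvs1_window()), window)
  }, USE.NAMES = FALSE, "")
  hit <- dkey %in% qkey
  if (require_haplogroup) {
    qmap <- split(qhg, qkey)
    hit <- vapply(seq_len(nrow(db)), function(i) {
      if (!dkey[i] %in% qkey) return(FALSE)
      allowed <- qmap[[dkey[i]]]
      any(is.na(allowed)) || is.na(db$haplogroup[i]) ||
        db$haplogroup[i] %in% allowed
    }, TRUE)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(db)), db$population),
    function(idx) {
      carried <- unique(dkey[idx][hit[idx]])
      data.frame(population = db$population[idx[1]],
                 n_individuals = length(idx),
                 n_shared_haplotypes = length(carried),
                 pct_shared_haplotypes =
                   100 * length(carried) / length(qkey),
                 n_carriers = sum(hit[idx]),
                 pct_carriers = 100 * sum(hit[idx]) / length(idx))
    }))
  rownames(out) <- NULL
  out
}

# FST from haplotype count vectors of the two populations (same levels).
.fst_from_counts <- function(ca, cb) {
  na <- sum(ca); nb <- sum(cb); n_tot <- na + nb
  ct <- ca + cb
  pairs <- function(m) sum(m * (m - 1) / 2)
  ssd_t <- (choose(n_tot, 2) - pairs(ct)) / n_tot
  ssd_w <- (choose(na, 2) - pairs(ca)) / na +
           (choose(nb, 2) - pairs(cb)) / nb
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a / 1
  ms_w <- ssd_w / (n_tot - 2)
  n_prime <- (n_tot - (na^2 + nb^2) / n_tot) / 1
  sigma_a <- (ms_a - ms_w) / n_prime
  sigma_w <- ms_w
  if (sigma_a + sigma_w == 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise FST between two population samples
#'
#' Haplotype-identity AMOVA FST between two samples of haplotype keys
#' (e.g. canonical motif strings over the comparison window).
#'
#' @param a,b Character vectors of haplotype identifiers, one element per
#'   individual; each sample needs at least 2 individuals.
#' @return FST estimate (may be negative; 0 when all individuals of both
#'   samples are identical).
#' @export
pairwise_fst <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each population sample needs >= 2 individuals")
  }
  lev <- unique(c(a, b))
  ca <- tabulate(match(a, lev), length(lev))
  cb <- tabulate(match(b, lev), length(lev))
  .fst_from_counts(ca, cb)
}

#' Permutation test of pairwise FST
#'
#' Permutes individuals between the two samples (sample sizes preserved)
#' and reports the add-one permutation p-value
#' `(1 + #\{FST_perm >= FST_obs\}) / (1 + n_perm)`; ties count as
#' exceedances, so the reported p is never 0.
#'
#' @param a,b As in [pairwise_fst()].
#' @param n_perm Number of permutations (>= 100; the reference setting is
#'   10,000).
#' @param seed Mandatory integer seed.
#' @return List with `fst`, `p_raw`, `n_perm`, `seed`.
#' @export
fst_permutation_test <- function(a, b, n_perm = 10000L, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_perm >= 100L)
  a <- as.character(a); b <- as.character(b)
  obs <- pairwise_fst(a, b)
  pool <- c(a, b)
  lev <- unique(pool)
  f <- match(pool, lev)
  na <- length(a); n_tot <- length(pool)
  ct <- tabulate(f, length(lev))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n_tot, na)
    ca <- tabulate(f[idx], length(lev))
    if (.fst_from_counts(ca, ct - ca) >= obs) exceed <- exceed + 1L
  }
  list(fst = obs, p_raw = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values;
#' monotone, capped at 1, input order preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pool populations into regional groups
#'
#' Concatenates the individuals of the member populations of each region.
#' Every population must be mapped or explicitly excluded (map it to
#' `"exclude"`); an unmapped population is an error.
#'
#' @param db Haplotype database (see [shared_haplotypes()]).
#' @param region_map Named character vector `population -> region`.
#' @return The database with `population` replaced by the region label;
#'   populations mapped to `"exclude"` are dropped.
#' @export
pool_populations <- function(db, region_map) {
  stopifnot(is.data.frame(db), "population" %in% names(db))
  unmapped <- setdiff(unique(db$population), names(region_map))
  if (length(unmapped)) {
    stop("unmapped population(s): ", paste(unmapped, collapse = ", "))
  }
  db$population <- unname(region_map[db$population])
  db[db$population != "exclude", , drop = FALSE]
}

#' FST of one query population against every database population
#'
#' Computes permutation-tested pairwise FST between a query sample and
#' each population of the database, adjusting the p-values across the
#' whole family with [bh_adjust()].
#'
#' @param query_keys Character vector of query haplotype keys.
#' @param db Haplotype database; motifs are reduced to keys over `window`.
#' @param window Comparison window.
#' @param n_perm,seed Passed to [fst_permutation_test()]; each comparison
#'   uses a seed derived deterministically from `seed`.
#' @return Data frame `population`, `n`, `fst`, `p_raw`, `p_adjusted`.
#' @export
fst_scan <- function(query_keys, db, window = hvs1_window(),
                     n_perm = 10000L, seed) {
  if (missing(seed)) stop("`seed` is required")
  dkey <- vapply(db$motif, function(m) {
    motif_key(parse_motif(m, window = hvs1_window()), window)
  }, USE.NAMES = FALSE, "")
  pops <- split(dkey, db$population)
  res <- do.call(rbind, lapply(seq_along(pops), function(i) {
    r <- fst_permutation_test(query_keys, pops[[i]], n_perm = n_perm,
                              seed = seed + i)
    data.frame(population = names(pops)[i], n = length(pops[[i]]),
               fst = r$fst, p_raw = r$p_raw)
  }))
  res$p_adjusted <- bh_adjust(res$p_raw)
  res
}
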
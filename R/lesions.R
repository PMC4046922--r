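# Miscoding-lesion typing and the per-clone, per-nucleotide lesion rate.

#' Classify miscoding lesions in an amplicon's clones
#'
#' Records every substitution of a non-contaminant clone against the
#' amplicon consensus outside the poly-C exclusion (primer-annealing sites
#' fall outside the fragment windows and are never scored).  A->G and T->C
#' changes are type 1 lesions; C->T and G->A changes (cytosine deamination
#' seen on either strand) are type 2; all other substitutions and indels
#' are `"other"`.
#'
#' @param clones Labelled clone table rows of a single amplicon.
#' @param consensus The amplicon consensus haplotype; when `NULL` it is
#'   recomputed with [per_amplicon_consensus()].
#' @param ref A [reference_segment()].
#' @return Data frame with columns `clone_id`, `position`, `ref_base`
#'   (consensus state), `observed_base`, `lesion_type`.
#' @export
classify_lesions <- function(clones, consensus = NULL,
                             ref = synthetic_hvs1_reference()) {
  clones <- as_clone_table(clones)
  if (!nrow(clones)) stop("empty clone set")
  keep <- !clones$origin %in% c("staff_contaminant", "carry_over")
  clones <- clones[keep, , drop = FALSE]
  if (!nrow(clones)) {
    return(data.frame(clone_id = character(0), position = integer(0),
                      ref_base = character(0), observed_base = character(0),
                      lesion_type = character(0)))
  }
  if (is.null(consensus)) {
    consensus <- per_amplicon_consensus(clones, ref)$haplotype
  }
  haps <- .amplicon_haplotypes(clones, ref)
  excl <- excluded_positions(ref)
  win <- .fragment_window(clones$fragment_id[1])
  out <- do.call(rbind, lapply(seq_along(haps), function(i) {
    d <- .clone_diffs(haps[[i]], consensus, ref)
    d <- d[!(d$position %in% excl) &
             d$position >= win[1] & d$position <= win[2], , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(clone_id = clones$clone_id[i], position = d$position,
               ref_base = d$expected, observed_base = d$observed,
               lesion_type = d$type)
  }))
  if (is.null(out)) {
    out <- data.frame(clone_id = character(0), position = integer(0),
                      ref_base = character(0), observed_base = character(0),
                      lesion_type = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Lesion rate per clone and nucleotide
#'
#' Normalises lesion counts by the number of clones and the number of
#' scored base pairs: the pooled estimate (default) is the total number of
#' lesion records across a sample's cloned amplicons divided by
#' `sum(n_clones * n_scored_bases)` over amplicons, where scored bases
#' exclude the poly-C interval (and primer sites, which lie outside the
#' fragment windows).  The `"per_pcr_mean"` variant averages per-amplicon
#' rates instead; it is exposed because either reading of the published
#' normalisation is defensible, but the pooled form matches the
#' per-clone-per-nucleotide unit and weights amplicons by the data they
#' contribute.
#'
#' @param records Lesion records from [classify_lesions()], concatenated
#'   over the sample's amplicons, each tagged with an `amplicon_id` column
#'   when `method = "per_pcr_mean"` is used.
#' @param exposures Data frame with one row per cloned amplicon: columns
#'   `amplicon_id`, `n_clones` (non-contaminant clones) and
#'   `n_scored_bases`.
#' @param method `"pooled"` (default) or `"per_pcr_mean"`.
#' @return Lesion rate (lesions per clone per nucleotide).
#' @export
lesion_rate <- function(records, exposures,
                        method = c("pooled", "per_pcr_mean")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(exposures),
            all(c("amplicon_id", "n_clones", "n_scored_bases") %in%
                  names(exposures)))
  denom <- exposures$n_clones * exposures$n_scored_bases
  if (sum(denom) <= 0) stop("undefined lesion rate: zero scored bases")
  n_lesions <- if (is.null(records)) 0L else nrow(records)
  if (method == "pooled") {
    return(n_lesions / sum(denom))
  }
  counts <- if (n_lesions) {
    stopifnot("amplicon_id" %in% names(records))
    tab <- table(factor(records$amplicon_id,
                        levels = exposures$amplicon_id))
    as.integer(tab)
  } else {
    rep(0L, nrow(exposures))
  }
  mean(counts / denom)
}

#' Full lesion analysis of one sample
#'
#' Convenience wrapper: groups a labelled clone table by amplicon, calls
#' the per-amplicon consensus, classifies lesions and returns the pooled
#' lesion rate together with the record and exposure tables.
#'
#' @param clones Labelled clone table of one sample.
#' @param ref A [reference_segment()].
#' @param method Passed to [lesion_rate()].
#' @return List with `rate`, `records`, `exposures`.
#' @export
sample_lesion_analysis <- function(clones, ref = synthetic_hvs1_reference(),
                                   method = "pooled") {
  clones <- as_clone_table(clones)
  keep <- !clones$origin %in% c("staff_contaminant", "carry_over")
  clones_ok <- clones[keep, , drop = FALSE]
  if (!nrow(clones_ok)) stop("no non-contaminant clones")
  amp_key <- interaction(clones_ok$extraction_id, clones_ok$pcr_id,
                         clones_ok$fragment_id, drop = TRUE)
  amps <- split(clones_ok, amp_key)
  records <- NULL
  exposures <- do.call(rbind, lapply(names(amps), function(k) {
    a <- amps[[k]]
    n_scored <- length(fragment_scored_positions(a$fragment_id[1], ref))
    r <- classify_lesions(a, ref = ref)
    if (nrow(r)) {
      r$amplicon_id <- k
      records <<- rbind(records, r)
    }
    data.frame(amplicon_id = k, n_clones = nrow(a),
               n_scored_bases = n_scored)
  }))
  list(rate = lesion_rate(records, exposures, method = method),
       records = records, exposures = exposures)
}

#' Screening decisions and endogenous-DNA recovery ratio
#'
#' Applies the screening rule - a sample is discarded at the first run of
#' two consecutive negative amplifications - to a chronological
#' amplification log, and reports the recovery ratio as validated skeletons
#' over total skeletons, in percent to one decimal.
#'
#' @param amplification_log Data frame with columns `sample_id` and
#'   `outcome` (`"positive"`/`"negative"`, abbreviations `pos`/`neg`
#'   accepted), rows in chronological order within each sample.
#' @param roster Character vector of all sampled skeleton identifiers
#'   (the recovery denominator).
#' @param validated Character vector of skeletons with validated profiles.
#' @return List with `decisions` (data frame `sample_id`, `discarded`,
#'   `discarded_at` index) and `recovery_ratio` (percent, one decimal).
#' @export
screening_and_recovery <- function(amplification_log, roster,
                                   validated = character(0)) {
  stopifnot(is.data.frame(amplification_log),
            all(c("sample_id", "outcome") %in% names(amplification_log)))
  if (!nrow(amplification_log)) stop("empty amplification log")
  out <- tolower(substr(amplification_log$outcome, 1, 3))
  if (!all(out %in% c("pos", "neg"))) {
    stop("outcome must be positive/negative")
  }
  neg <- out == "neg"
  decisions <- do.call(rbind, lapply(
    split(seq_len(nrow(amplification_log)), amplification_log$sample_id),
    function(idx) {
      n <- neg[idx]
      run2 <- which(n[-1] & n[-length(n)])
      data.frame(sample_id = amplification_log$sample_id[idx[1]],
                 discarded = length(run2) > 0,
                 discarded_at = if (length(run2)) run2[1] + 1L else
                   NA_integer_)
    }))
  rownames(decisions) <- NULL
  stopifnot(length(roster) > 0)
  ratio <- round(100 * length(intersect(unique(validated), roster)) /
                   length(unique(roster)), 1)
  list(decisions = decisions, recovery_ratio = ratio)
}
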
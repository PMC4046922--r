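# Authentication engine: clone-origin labelling, per-amplicon majority
# consensus, and reproducibility-validated sample consensus calling.
#
# Clones are kept in long-format data frames with columns
#   clone_id, sample_id, extraction_id, pcr_id, fragment_id, batch_id,
#   motif, origin
# where `motif` is the clone's haplotype over its fragment window and
# `origin` is one of "endogenous", "staff_contaminant", "carry_over",
# "unclassified".

.clone_cols <- c("clone_id", "sample_id", "extraction_id", "pcr_id",
                 "fragment_id", "batch_id", "motif", "origin")

#' Validate a clone table
#'
#' @param clones Data frame of clone records (see package overview for the
#'   column contract).  A missing `origin` column is initialised to
#'   `"unclassified"`; a missing `batch_id` to `NA`.
#' @return The validated clone table.
#' @export
as_clone_table <- function(clones) {
  stopifnot(is.data.frame(clones))
  if (is.null(clones$origin)) clones$origin <- "unclassified"
  if (is.null(clones$batch_id)) clones$batch_id <- NA_character_
  missing <- setdiff(.clone_cols, names(clones))
  if (length(missing)) {
    stop("clone table lacks column(s): ", paste(missing, collapse = ", "))
  }
  fr <- amplicon_fragments()
  if (!all(clones$fragment_id %in% fr$fragment_id)) {
    stop("unregistered fragment_id in clone table")
  }
  clones
}

# window of a fragment
.fragment_window <- function(fragment_id) {
  fr <- amplicon_fragments()
  row <- fr[fr$fragment_id == fragment_id, ]
  if (nrow(row) != 1L) stop("unknown fragment_id: ", fragment_id)
  c(row$lo, row$hi)
}

# Parse the motifs of one amplicon's clones into a list of haplotypes over
# the fragment window (poly-C positions removed).
.amplicon_haplotypes <- function(clones, ref) {
  win <- .fragment_window(clones$fragment_id[1])
  excl <- excluded_positions(ref)
  lapply(clones$motif, function(m) {
    h <- parse_motif(m, window = win)
    keep <- !(h$positions %in% excl)
    haplotype(h$positions[keep], h$bases[keep], window = win)
  })
}

# State of a haplotype at given positions: the variant base where present,
# the reference base otherwise.
.state_at <- function(h, positions, ref) {
  st <- ref_base(ref, positions)
  if (length(h$positions)) {
    idx <- match(h$positions, positions)
    st[idx[!is.na(idx)]] <- h$bases[!is.na(idx)]
  }
  st
}

#' Majority consensus of one amplicon's clones
#'
#' Calls the per-position majority state among the amplicon's clones,
#' excluding clones labelled `staff_contaminant` or `carry_over`.  Ties are
#' resolved to the reference base and flagged ambiguous.  Positions in the
#' poly-C exclusion never enter the consensus.
#'
#' @param clones Clone table rows of a single amplicon (one
#'   sample/extraction/PCR/fragment combination).
#' @param ref A [reference_segment()].
#' @param use_all If `TRUE`, contaminant-labelled clones are included
#'   (used internally to form the provisional majority before labelling).
#' @return A list with `haplotype` (the consensus over the fragment
#'   window), `support` (data frame: position, base, n_support, n_clones,
#'   ambiguous), and `n_clones` used.
#' @export
per_amplicon_consensus <- function(clones, ref = synthetic_hvs1_reference(),
                                   use_all = FALSE) {
  clones <- as_clone_table(clones)
  if (!nrow(clones)) stop("empty clone set")
  key <- unique(clones[c("sample_id", "extraction_id", "pcr_id",
                         "fragment_id")])
  if (nrow(key) != 1L) {
    stop("clones from more than one amplicon passed to ",
         "per_amplicon_consensus()")
  }
  if (!use_all) {
    clones <- clones[!clones$origin %in%
                       c("staff_contaminant", "carry_over"), , drop = FALSE]
    if (!nrow(clones)) {
      stop("no endogenous signal: all clones of amplicon are ",
           "labelled contaminant")
    }
  }
  win <- .fragment_window(clones$fragment_id[1])
  haps <- .amplicon_haplotypes(clones, ref)
  n <- length(haps)
  pos_all <- sort(unique(unlist(lapply(haps, `[[`, "positions"))))
  if (!length(pos_all)) {
    return(list(haplotype = haplotype(window = win),
                support = data.frame(position = integer(0),
                                     base = character(0),
                                     n_support = integer(0),
                                     n_clones = integer(0),
                                     ambiguous = logical(0)),
                n_clones = n))
  }
  states <- vapply(haps, .state_at, character(length(pos_all)),
                   positions = pos_all, ref = ref)
  states <- matrix(states, nrow = length(pos_all))
  refb <- ref_base(ref, pos_all)
  cons_base <- character(length(pos_all))
  supp <- integer(length(pos_all))
  amb <- logical(length(pos_all))
  for (i in seq_along(pos_all)) {
    tab <- table(states[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      # tie: conservative toward the reference
      cons_base[i] <- if (refb[i] %in% top) refb[i] else sort(top)[1]
      amb[i] <- TRUE
    } else {
      cons_base[i] <- top
    }
    supp[i] <- sum(states[i, ] == cons_base[i])
  }
  var_idx <- which(cons_base != refb)
  list(
    haplotype = haplotype(pos_all[var_idx], cons_base[var_idx],
                          window = win),
    support = data.frame(position = pos_all[var_idx],
                         base = cons_base[var_idx],
                         n_support = supp[var_idx],
                         n_clones = rep(n, length(var_idx)),
                         ambiguous = amb[var_idx]),
    n_clones = n,
    ambiguous_positions = pos_all[amb]
  )
}

# Differences of a clone against a target haplotype over scored positions.
# Returns data frame (position, expected, observed, type).
.clone_diffs <- function(clone_h, target_h, ref) {
  pos <- sort(union(clone_h$positions, target_h$positions))
  if (!length(pos)) {
    return(data.frame(position = integer(0), expected = character(0),
                      observed = character(0), type = character(0)))
  }
  exp_st <- .state_at(target_h, pos, ref)
  obs_st <- .state_at(clone_h, pos, ref)
  d <- exp_st != obs_st
  data.frame(position = pos[d], expected = exp_st[d], observed = obs_st[d],
             type = substitution_type(exp_st[d], obs_st[d]))
}

#' Type a substitution as a miscoding-lesion class
#'
#' Type 1 lesions are A->G or T->C changes; type 2 lesions (cytosine
#' deamination and its complement) are C->T or G->A.  Everything else,
#' including indels, is `"other"`.
#'
#' @param from,to Character vectors of expected and observed states.
#' @return Character vector in `c("type1", "type2", "other")`.
#' @export
substitution_type <- function(from, to) {
  out <- rep("other", length(from))
  out[(from == "A" & to == "G") | (from == "T" & to == "C")] <- "type1"
  out[(from == "C" & to == "T") | (from == "G" & to == "A")] <- "type2"
  out
}

#' Label clone origins within one amplicon
#'
#' Classifies each clone of an amplicon against the amplicon's provisional
#' majority consensus, the staff panel, and consensus motifs of other
#' samples processed in the same batch:
#' * `endogenous` - equals the majority, or differs from it only by
#'   lesion-typed substitutions (damage on the endogenous template);
#' * `staff_contaminant` - equals a staff motif over the fragment window
#'   while differing from the majority;
#' * `carry_over` - equals the motif of a different sample from the same
#'   batch while differing from the majority;
#' * `unclassified` - anything else.
#'
#' @param clones Clone table rows of a single amplicon.
#' @param staff Staff panel: data frame with columns `person_id`, `motif`,
#'   or `NULL` (staff check skipped with a warning).
#' @param batch_neighbors Data frame with columns `sample_id`, `motif` of
#'   consensus profiles from other samples of the same batch, or `NULL`.
#' @param ref A [reference_segment()].
#' @return The clone table with the `origin` column filled in.
#' @export
label_clone_origins <- function(clones, staff = NULL,
                                batch_neighbors = NULL,
                                ref = synthetic_hvs1_reference()) {
  clones <- as_clone_table(clones)
  if (!nrow(clones)) stop("empty clone set")
  win <- .fragment_window(clones$fragment_id[1])
  excl <- excluded_positions(ref)
  trim_key <- function(motif) {
    h <- trim_to_window(parse_motif(motif, window = hvs1_window()), win)
    keep <- !(h$positions %in% excl)
    format_motif(haplotype(h$positions[keep], h$bases[keep], window = win))
  }
  maj <- per_amplicon_consensus(clones, ref, use_all = TRUE)
  maj_key <- format_motif(maj$haplotype)
  staff_keys <- character(0)
  if (is.null(staff) || !nrow(as.data.frame(staff))) {
    warning("staff panel empty: staff-contamination check skipped")
  } else {
    staff <- as.data.frame(staff)
    stopifnot(all(c("person_id", "motif") %in% names(staff)))
    staff_keys <- vapply(staff$motif, trim_key, "")
  }
  neigh_keys <- character(0)
  if (!is.null(batch_neighbors) && nrow(as.data.frame(batch_neighbors))) {
    bn <- as.data.frame(batch_neighbors)
    stopifnot(all(c("sample_id", "motif") %in% names(bn)))
    bn <- bn[bn$sample_id != clones$sample_id[1], , drop = FALSE]
    neigh_keys <- vapply(bn$motif, trim_key, "")
  }
  haps <- .amplicon_haplotypes(clones, ref)
  clones$origin <- vapply(haps, function(h) {
    key <- format_motif(h)
    if (key == maj_key) return("endogenous")
    if (key %in% staff_keys) return("staff_contaminant")
    if (key %in% neigh_keys) return("carry_over")
    d <- .clone_diffs(h, maj$haplotype, ref)
    if (nrow(d) && all(d$type %in% c("type1", "type2"))) {
      return("endogenous")
    }
    "unclassified"
  }, "")
  clones
}

#' Call a sample's reproducibility-validated consensus profile
#'
#' A variant enters the sample consensus iff it appears in the per-amplicon
#' consensus of at least `min_independent` amplifications from independent
#' extractions; when the sample has a single extraction, independent PCRs
#' are accepted instead (`independence = "auto"`, the default).  Fragments
#' lacking independent replication contribute no coverage, so the profile's
#' covered window is the union of replicated fragment windows.  SNP typings
#' are marked validated iff replicated in at least two extracts.
#'
#' @param clones Labelled clone table of one sample (all amplicons); run
#'   [label_clone_origins()] per amplicon first.
#' @param snp_typings Data frame with columns `position`, `base`,
#'   `extraction_id`, or `NULL`.
#' @param ref A [reference_segment()].
#' @param min_independent Minimum number of independent amplifications
#'   attesting a variant (default 2).
#' @param independence `"auto"` (extractions when >1 exist, else PCRs),
#'   `"extraction"` or `"pcr"`.
#' @return An object of class `consensus_profile`: sample_id, `haplotype`,
#'   `status` (`"validated"`, `"provisional"` or `"discarded"`), `support`,
#'   `dropped` (non-reproducible amplicon-consensus variants), `snp_typings`
#'   (position, base, validated), `fragments` replication summary.
#' @export
call_sample_consensus <- function(clones, snp_typings = NULL,
                                  ref = synthetic_hvs1_reference(),
                                  min_independent = 2L,
                                  independence = c("auto", "extraction",
                                                   "pcr")) {
  independence <- match.arg(independence)
  clones <- as_clone_table(clones)
  if (!nrow(clones)) stop("empty clone table")
  sample_id <- unique(clones$sample_id)
  if (length(sample_id) != 1L) {
    stop("call_sample_consensus() expects a single sample")
  }
  keep <- !clones$origin %in% c("staff_contaminant", "carry_over")
  clones_ok <- clones[keep, , drop = FALSE]

  amp_key <- interaction(clones_ok$extraction_id, clones_ok$pcr_id,
                         clones_ok$fragment_id, drop = TRUE)
  amp_list <- split(clones_ok, amp_key)
  amp_list <- Filter(nrow, amp_list)
  if (!length(amp_list)) {
    return(structure(list(sample_id = sample_id, haplotype = NULL,
                          status = "discarded",
                          reason = "no non-contaminant amplicons",
                          support = NULL, dropped = NULL,
                          snp_typings = .validate_snps(snp_typings),
                          fragments = NULL),
                     class = "consensus_profile"))
  }

  cons <- lapply(amp_list, per_amplicon_consensus, ref = ref)
  meta <- do.call(rbind, lapply(amp_list, function(a) {
    a[1, c("extraction_id", "pcr_id", "fragment_id")]
  }))
  n_extracts <- length(unique(meta$extraction_id))
  unit <- switch(independence,
                 auto = if (n_extracts >= 2L) "extraction_id" else "pcr_id",
                 extraction = "extraction_id",
                 pcr = "pcr_id")
  meta$unit <- if (unit == "pcr_id") {
    paste(meta$extraction_id, meta$pcr_id, sep = "/")
  } else {
    as.character(meta[[unit]])
  }

  # fragment replication: a fragment is covered iff attested by
  # >= min_independent independent units
  frag_tab <- do.call(rbind, lapply(split(seq_along(amp_list),
                                          meta$fragment_id),
    function(idx) {
      data.frame(fragment_id = meta$fragment_id[idx[1]],
                 n_amplicons = length(idx),
                 n_units = length(unique(meta$unit[idx])))
    }))
  frag_tab$replicated <- frag_tab$n_units >= min_independent
  covered <- frag_tab$fragment_id[frag_tab$replicated]
  if (!length(covered)) {
    return(structure(list(sample_id = sample_id, haplotype = NULL,
                          status = "discarded",
                          reason = paste0("no fragment replicated in >= ",
                                          min_independent,
                                          " independent amplifications"),
                          support = NULL, dropped = NULL,
                          snp_typings = .validate_snps(snp_typings),
                          fragments = frag_tab),
                     class = "consensus_profile"))
  }
  fr <- amplicon_fragments()
  win <- c(min(fr$lo[fr$fragment_id %in% covered]),
           max(fr$hi[fr$fragment_id %in% covered]))

  # variant attestation across amplicon consensuses
  var_tab <- do.call(rbind, lapply(seq_along(cons), function(i) {
    h <- cons[[i]]$haplotype
    if (!length(h$positions)) return(NULL)
    data.frame(position = h$positions, base = h$bases,
               fragment_id = meta$fragment_id[i], unit = meta$unit[i],
               extraction_id = meta$extraction_id[i],
               pcr_id = meta$pcr_id[i])
  }))
  support <- dropped <- data.frame(position = integer(0),
                                   base = character(0),
                                   n_amplicons = integer(0),
                                   n_units = integer(0))
  if (!is.null(var_tab) && nrow(var_tab)) {
    agg <- do.call(rbind, lapply(
      split(var_tab, paste(var_tab$position, var_tab$base)),
      function(v) data.frame(position = v$position[1], base = v$base[1],
                             fragment_id = v$fragment_id[1],
                             n_amplicons = nrow(v),
                             n_units = length(unique(v$unit)))))
    agg <- agg[order(agg$position), , drop = FALSE]
    ok <- agg$n_units >= min_independent & agg$fragment_id %in% covered
    support <- agg[ok, c("position", "base", "n_amplicons", "n_units")]
    dropped <- agg[!ok, c("position", "base", "n_amplicons", "n_units")]
  }
  # a position covered by both fragments may be attested twice; dedupe
  support <- support[!duplicated(support$position), , drop = FALSE]
  h <- haplotype(support$position, support$base, window = win)

  snps <- .validate_snps(snp_typings)
  structure(list(sample_id = sample_id, haplotype = h,
                 status = "validated", reason = NULL,
                 support = support, dropped = dropped,
                 snp_typings = snps, fragments = frag_tab,
                 independence = unit),
            class = "consensus_profile")
}

# collapse raw SNP typings (position, base, extraction_id) into per-position
# calls with a validated flag (replicated in >= 2 extracts, consistent base)
.validate_snps <- function(snp_typings) {
  empty <- data.frame(position = integer(0), base = character(0),
                      validated = logical(0))
  if (is.null(snp_typings) || !nrow(as.data.frame(snp_typings))) return(empty)
  s <- as.data.frame(snp_typings)
  stopifnot(all(c("position", "base", "extraction_id") %in% names(s)))
  out <- do.call(rbind, lapply(split(s, s$position), function(v) {
    tab <- table(v$base)
    base <- names(tab)[which.max(tab)]
    consistent <- length(tab) == 1L
    n_extr <- length(unique(v$extraction_id[v$base == base]))
    data.frame(position = v$position[1], base = base,
               validated = consistent && n_extr >= 2L)
  }))
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile> ", x$sample_id, "  status: ", x$status, "\n",
      sep = "")
  if (!is.null(x$haplotype)) {
    cat("  motif: ", format_motif(x$haplotype), "  window [",
        x$haplotype$window[1], ", ", x$haplotype$window[2], "]\n", sep = "")
  }
  if (!is.null(x$reason)) cat("  reason: ", x$reason, "\n", sep = "")
  invisible(x)
}
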
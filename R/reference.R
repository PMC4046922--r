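# Reference-segment representation shared by all pipeline stages.
# All coordinates in this package are 1-based inclusive rCRS positions.

#' Create a reference segment
#'
#' A reference segment is a stretch of mitochondrial reference sequence with
#' an absolute 1-based start coordinate and an optional poly-C exclusion
#' interval.  Positions inside the exclusion interval are ignored by every
#' consumer (variant calling, lesion scoring, simulation), so the exclusion
#' is applied uniformly across the pipeline.
#'
#' @param name Identifier for the segment (e.g. `"HVS1"`).
#' @param start 1-based position of the first base of `sequence`.
#' @param sequence Uppercase DNA string over the alphabet `A`, `C`, `G`, `T`.
#' @param polyc_exclusion Length-2 integer vector `c(lo, hi)` giving the
#'   closed interval of positions excluded from scoring (the homopolymeric
#'   cytosine tract), or `NULL` for none.  Default `c(16182, 16193)`.
#' @return An object of class `reference_segment`.
#' @export
reference_segment <- function(name, start, sequence,
                              polyc_exclusion = c(16182L, 16193L)) {
  stopifnot(is.character(name), length(name) == 1L)
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop("`start` must be a positive integer")
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("`sequence` must be non-empty")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("`sequence` contains characters outside {A,C,G,T}")
  }
  end <- start + length(bases) - 1L
  if (!is.null(polyc_exclusion)) {
    polyc_exclusion <- as.integer(polyc_exclusion)
    stopifnot(length(polyc_exclusion) == 2L,
              polyc_exclusion[1] <= polyc_exclusion[2])
    if (polyc_exclusion[1] < start || polyc_exclusion[2] > end) {
      stop("`polyc_exclusion` must lie within the segment [",
           start, ", ", end, "]")
    }
  }
  structure(
    list(name = name, start = start, end = end, bases = bases,
         polyc_exclusion = polyc_exclusion),
    class = "reference_segment"
  )
}

#' @export
print.reference_segment <- function(x, ...) {
  cat("<reference_segment> ", x$name, "  [", x$start, ", ", x$end, "]",
      sep = "")
  if (!is.null(x$polyc_exclusion)) {
    cat("  poly-C excluded: [", x$polyc_exclusion[1], ", ",
        x$polyc_exclusion[2], "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Reference base(s) at given positions
#'
#' @param ref A [reference_segment()].
#' @param positions Integer vector of 1-based rCRS positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, positions) {
  stopifnot(inherits(ref, "reference_segment"))
  positions <- as.integer(positions)
  idx <- positions - ref$start + 1L
  if (any(idx < 1L | idx > length(ref$bases))) {
    stop("position outside reference segment [", ref$start, ", ",
         ref$end, "]")
  }
  ref$bases[idx]
}

#' Positions of a reference segment excluded from scoring
#'
#' @param ref A [reference_segment()].
#' @return Integer vector of positions in the poly-C exclusion interval
#'   (empty when none is set).
#' @export
excluded_positions <- function(ref) {
  if (is.null(ref$polyc_exclusion)) return(integer(0))
  seq.int(ref$polyc_exclusion[1], ref$polyc_exclusion[2])
}

#' The analysis window of hypervariable segment I
#'
#' The HVS1 window considered throughout the pipeline, np 16,126-16,369.
#'
#' @return Integer vector `c(16126, 16369)`.
#' @export
hvs1_window <- function() c(16126L, 16369L)

# Synthetic control-region reference, np 16,095-16,400.  This is NOT the
# published rCRS sequence: it is a deterministic synthetic stand-in with the
# documented rCRS alleles fixed at the positions the fixture motifs and the
# decision table touch (16126 T, 16223 C, 16224 T, 16256 C, 16293 A, 16294 C,
# 16298 T, 16311 T, 16356 T, 16366 C, ...), and a 12-base cytosine tract at
# np 16,182-16,193 emulating the poly-C region.  Everything the package
# computes is reference-relative, so any segment with these alleles fixed
# yields identical motifs, lesion types and population statistics.
.synthetic_hvs1_seq <- paste0(
  "ACCCTCAATGCTATTCTAACACCAGTAGTTTTGTGGCGGGCGTGTTTCGTGCACCGACCT",
  "GGCTCTTAACCGATACCTTAAGCTTACCCCCCCCCCCCCTTAATTGACATCAGTTTGTGG",
  "TGTACATCCTAAAACCTGACTATACAGACCACATTCTCGATCTTTTCTTCTCGTCCATTG",
  "CACCAATTCCGTACCCTCACCAATATAACTACATAATCCCGAGAGCGAAATGGCCAACAT",
  "TTTTAAAGATATTAGAACTCCTCAACATAAACAATAACTACAGCCCATCCGGCTACACAT",
  "ACAGCC"
)

#' Synthetic HVS1 reference segment
#'
#' Returns the synthetic control-region reference segment (np 16,095-16,400)
#' bundled with the package.  The segment is a deterministic synthetic
#' stand-in for the revised Cambridge Reference Sequence restricted to the
#' amplified HVS1 region: the reference alleles at every position used by
#' the packaged fixture and the default decision table match the published
#' rCRS alleles, and np 16,182-16,193 is a cytosine tract carrying the
#' default poly-C exclusion.  Because haplotypes are represented as
#' reference-relative variant sets, all motif, lesion and population-level
#' computations are invariant to the filler bases.
#'
#' @return A [reference_segment()] named `"synthetic-HVS1"`.
#' @export
synthetic_hvs1_reference <- function() {
  reference_segment("synthetic-HVS1", 16095L, .synthetic_hvs1_seq)
}

#' Amplicon fragment definitions
#'
#' The two overlapping HVS1 amplicons used for cloning: fragment 1 spans
#' np 16,126-16,258 and fragment 2 spans np 16,258-16,369.  Positions are
#' the sequence read between the primers, so primer-annealing sites fall
#' outside these windows and are never scored.
#'
#' @return A data frame with columns `fragment_id`, `lo`, `hi`.
#' @export
amplicon_fragments <- function() {
  data.frame(fragment_id = c(1L, 2L),
             lo = c(16126L, 16258L),
             hi = c(16258L, 16369L))
}

#' Scored positions of an amplicon fragment
#'
#' The positions of a fragment window that enter consensus support and
#' lesion counting: the fragment window minus the reference segment's
#' poly-C exclusion interval.
#'
#' @param fragment_id 1 or 2 (see [amplicon_fragments()]).
#' @param ref A [reference_segment()]; defaults to the synthetic reference.
#' @return Integer vector of scored positions.
#' @export
fragment_scored_positions <- function(fragment_id,
                                      ref = synthetic_hvs1_reference()) {
  fr <- amplicon_fragments()
  row <- fr[fr$fragment_id == fragment_id, ]
  if (nrow(row) != 1L) stop("unknown fragment_id: ", fragment_id)
  pos <- seq.int(row$lo, row$hi)
  setdiff(pos, excluded_positions(ref))
}
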
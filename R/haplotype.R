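# Reference-relative haplotype representation and the motif grammar.
#
# A haplotype is a set of substitutions (or deletions) relative to the
# reference within a stated covered window.  The motif grammar is
# whitespace-separated tokens "<position><base>" for substitutions and
# "<position>d" for deletions; the literal "CRS" denotes the empty set.
# Insertions are outside the grammar and rejected.

#' Construct a haplotype
#'
#' @param positions Integer vector of 1-based rCRS positions (may be empty).
#' @param bases Character vector of derived states, one per position: a base
#'   in `A`, `C`, `G`, `T` or `"-"` for a deletion.
#' @param window Length-2 integer vector `c(lo, hi)`, the closed interval of
#'   positions actually covered.  Defaults to the complete HVS1 window.
#' @param trimmed Logical flag set by [trim_to_window()] when trimming
#'   dropped variants.
#' @return An object of class `mito_haplotype`.
#' @export
haplotype <- function(positions = integer(0), bases = character(0),
                      window = hvs1_window(), trimmed = FALSE) {
  positions <- as.integer(positions)
  bases <- toupper(as.character(bases))
  window <- as.integer(window)
  if (length(window) != 2L || anyNA(window) || window[1] > window[2]) {
    stop("`window` must be c(lo, hi) with lo <= hi")
  }
  if (length(positions) != length(bases)) {
    stop("`positions` and `bases` must have equal length")
  }
  if (anyDuplicated(positions)) {
    stop("duplicate variant position: ",
         paste(positions[duplicated(positions)], collapse = ", "))
  }
  if (length(bases) && !all(bases %in% c("A", "C", "G", "T", "-"))) {
    stop("derived state must be one of A, C, G, T or '-'")
  }
  outside <- positions < window[1] | positions > window[2]
  if (any(outside)) {
    stop("variant position outside covered window [", window[1], ", ",
         window[2], "]: ", paste(positions[outside], collapse = ", "))
  }
  ord <- order(positions)
  structure(
    list(positions = positions[ord], bases = bases[ord], window = window,
         trimmed = isTRUE(trimmed)),
    class = "mito_haplotype"
  )
}

#' @export
print.mito_haplotype <- function(x, ...) {
  cat("<mito_haplotype> ", format_motif(x),
      "  window [", x$window[1], ", ", x$window[2], "]",
      if (x$trimmed) "  (trimmed)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.mito_haplotype <- function(x) length(x$positions)

#' Test two haplotypes for motif equality
#'
#' Equality compares the variant sets only; the covered window is ignored,
#' so identical motifs with different coverage compare equal (this is the
#' convention used for haplotype deduplication).
#'
#' @param a,b `mito_haplotype` objects.
#' @return Logical scalar.
#' @export
same_motif <- function(a, b) {
  stopifnot(inherits(a, "mito_haplotype"), inherits(b, "mito_haplotype"))
  identical(a$positions, b$positions) && identical(a$bases, b$bases)
}

#' Parse a haplotype motif string
#'
#' Parses whitespace-separated tokens `"<position><base>"` (substitution) or
#' `"<position>d"` (deletion); the literal `"CRS"` yields the empty variant
#' set.  Insertion notation (e.g. `16193.1C`) is rejected.
#'
#' @param text Motif string, e.g. `"16224C 16311C 16366T"` or `"CRS"`.
#' @param window Covered window, default the complete HVS1 window.
#' @return A [haplotype()].
#' @export
parse_motif <- function(text, window = hvs1_window()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (toupper(text) == "CRS" || text == "") {
    return(haplotype(window = window))
  }
  tokens <- strsplit(text, "\\s+")[[1]]
  m <- regmatches(tokens, regexec("^([0-9]+)([ACGTacgt]|d)$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed motif token: '", tokens[bad][1], "'")
  }
  positions <- vapply(m, function(x) as.integer(x[2]), 1L)
  bases <- vapply(m, function(x) x[3], "")
  bases <- ifelse(bases == "d", "-", toupper(bases))
  if (anyDuplicated(positions)) {
    stop("duplicate position in motif: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  }
  outside <- positions < window[1] | positions > window[2]
  if (any(outside)) {
    stop("motif token outside window [", window[1], ", ", window[2],
         "]: '", tokens[outside][1], "'")
  }
  haplotype(positions, bases, window = window)
}

#' Format a haplotype as a motif string
#'
#' Tokens are emitted sorted by position; the empty variant set renders as
#' `"CRS"`; deletions render as `"<position>d"`.
#'
#' @param h A [haplotype()].
#' @return Motif string.
#' @export
format_motif <- function(h) {
  stopifnot(inherits(h, "mito_haplotype"))
  if (!length(h$positions)) return("CRS")
  tok <- ifelse(h$bases == "-", paste0(h$positions, "d"),
                paste0(h$positions, h$bases))
  paste(tok, collapse = " ")
}

#' Call reference-relative variants from an aligned sequence
#'
#' Compares an aligned sequence (equal length to the reference segment,
#' gaps as `-`) to the reference base by base within a window, recording
#' substitutions and deletions.  Positions in the reference's poly-C
#' exclusion interval are ignored.
#'
#' @param seq Aligned DNA string (same length as the reference segment).
#' @param ref A [reference_segment()].
#' @param window Length-2 interval of positions to call over; default the
#'   intersection of the segment with the HVS1 window.
#' @return A [haplotype()] with `window` set to the calling window.
#' @export
variants_from_sequence <- function(seq, ref, window = hvs1_window()) {
  stopifnot(inherits(ref, "reference_segment"),
            is.character(seq), length(seq) == 1L)
  obs <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(obs) != length(ref$bases)) {
    stop("aligned sequence length (", length(obs),
         ") does not match reference segment length (",
         length(ref$bases), ")")
  }
  if (!all(obs %in% c("A", "C", "G", "T", "-", "N"))) {
    stop("sequence contains a character outside {A,C,G,T,-,N}")
  }
  window <- as.integer(window)
  lo <- max(window[1], ref$start); hi <- min(window[2], ref$end)
  if (lo > hi) stop("window does not overlap the reference segment")
  pos <- seq.int(lo, hi)
  pos <- setdiff(pos, excluded_positions(ref))
  idx <- pos - ref$start + 1L
  diff <- obs[idx] != ref$bases[idx] & obs[idx] != "N"
  haplotype(pos[diff], ifelse(obs[idx][diff] == "-", "-", obs[idx][diff]),
            window = c(lo, hi))
}

#' Reconstruct a sequence from a haplotype
#'
#' Substitutes the derived bases of `h` into the reference segment and
#' returns the full segment sequence (deletions render as `-`).  Inverse of
#' [variants_from_sequence()] on substitution-only haplotypes.
#'
#' @param h A [haplotype()].
#' @param ref A [reference_segment()] covering all variant positions.
#' @return DNA string of the same length as the reference segment.
#' @export
sequence_from_variants <- function(h, ref) {
  stopifnot(inherits(h, "mito_haplotype"), inherits(ref, "reference_segment"))
  if (length(h$positions) &&
      (min(h$positions) < ref$start || max(h$positions) > ref$end)) {
    stop("variant position outside reference segment [", ref$start, ", ",
         ref$end, "]")
  }
  bases <- ref$bases
  if (length(h$positions)) {
    bases[h$positions - ref$start + 1L] <- h$bases
  }
  paste(bases, collapse = "")
}

#' Restrict a haplotype to a window
#'
#' Variants outside the window are removed; the covered window becomes the
#' intersection of the haplotype's window with `window`.  The `trimmed`
#' flag is set when the operation dropped at least one variant.
#'
#' @param h A [haplotype()].
#' @param window Length-2 integer interval.
#' @return A [haplotype()] with updated window.
#' @export
trim_to_window <- function(h, window) {
  stopifnot(inherits(h, "mito_haplotype"))
  window <- as.integer(window)
  lo <- max(h$window[1], window[1]); hi <- min(h$window[2], window[2])
  if (lo > hi) {
    stop("degenerate window: [", window[1], ", ", window[2],
         "] does not intersect the haplotype window [",
         h$window[1], ", ", h$window[2], "]")
  }
  keep <- h$positions >= lo & h$positions <= hi
  haplotype(h$positions[keep], h$bases[keep], window = c(lo, hi),
            trimmed = h$trimmed || any(!keep))
}

#' Count distinct haplotypes
#'
#' Deduplicates a list of haplotypes on exact variant-set equality.  The
#' covered window is ignored, so identical motifs with different coverage
#' collapse into one haplotype.  Representatives are returned in order of
#' first occurrence.
#'
#' @param hs List of [haplotype()] objects (may be empty).
#' @param complete_only If `TRUE`, haplotypes whose window is narrower than
#'   `window` are excluded before deduplication.
#' @param window Reference window used by `complete_only`.
#' @return A list with `n_distinct`, `representatives` (list of haplotypes),
#'   and `assignment` (integer index of each input into the representative
#'   list; `NA` for inputs excluded as incomplete).
#' @export
distinct_haplotypes <- function(hs, complete_only = FALSE,
                                window = hvs1_window()) {
  stopifnot(is.list(hs))
  if (length(hs)) {
    stopifnot(all(vapply(hs, inherits, TRUE, "mito_haplotype")))
  }
  assignment <- rep(NA_integer_, length(hs))
  eligible <- seq_along(hs)
  if (complete_only && length(hs)) {
    ok <- vapply(hs, function(h) {
      h$window[1] <= window[1] && h$window[2] >= window[2]
    }, TRUE)
    eligible <- which(ok)
  }
  keys <- vapply(hs[eligible], format_motif, "")
  first <- !duplicated(keys)
  reps <- hs[eligible][first]
  assignment[eligible] <- match(keys, keys[first])
  list(n_distinct = length(reps), representatives = reps,
       assignment = assignment)
}

# Canonical motif key over a window; used for identity comparisons in the
# population analyses.
motif_key <- function(h, window = NULL) {
  if (!is.null(window)) h <- trim_to_window(h, window)
  format_motif(h)
}
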
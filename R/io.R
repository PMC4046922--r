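# Interchange formats: motif TSV (sample_id, motif, window_lo, window_hi,
# haplogroup), clone FASTA with structured headers
# (sample|extraction|pcr|fragment|clone), and the long-format clone TSV.

#' Read a motif table
#'
#' @param path TSV with columns `sample_id`, `motif`, `window_lo`,
#'   `window_hi` and optionally `haplogroup`.
#' @return Data frame; window columns default to the complete HVS1 window
#'   when absent.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  stopifnot(all(c("sample_id", "motif") %in% names(tab)))
  if (is.null(tab$window_lo)) tab$window_lo <- hvs1_window()[1]
  if (is.null(tab$window_hi)) tab$window_hi <- hvs1_window()[2]
  # validate every motif eagerly so malformed rows fail at load time
  for (i in seq_len(nrow(tab))) {
    parse_motif(tab$motif[i], window = c(tab$window_lo[i],
                                         tab$window_hi[i]))
  }
  tab
}

#' Write a motif table
#'
#' @param tab Data frame as returned by [read_motif_table()].
#' @param path Output TSV path.
#' @export
write_motif_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write clones as FASTA with structured headers
#'
#' Each clone's fragment-window sequence is reconstructed from its motif
#' against the reference; headers have the form
#' `sample|extraction|pcr|fragment|clone`.
#'
#' @param clones Clone table (see [as_clone_table()]).
#' @param path Output FASTA path.
#' @param ref A [reference_segment()].
#' @export
write_clone_fasta <- function(clones, path,
                              ref = synthetic_hvs1_reference()) {
  clones <- as_clone_table(clones)
  lines <- character(0)
  for (i in seq_len(nrow(clones))) {
    win <- .fragment_window(clones$fragment_id[i])
    h <- parse_motif(clones$motif[i], window = win)
    full <- sequence_from_variants(h, ref)
    seq <- substr(full, win[1] - ref$start + 1L, win[2] - ref$start + 1L)
    hdr <- paste(clones$sample_id[i], clones$extraction_id[i],
                 clones$pcr_id[i], clones$fragment_id[i],
                 clones$clone_id[i], sep = "|")
    lines <- c(lines, paste0(">", hdr), seq)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read clones from a structured-header FASTA
#'
#' Inverse of [write_clone_fasta()]: sequences are aligned to the
#' fragment window named in the header and converted back to motifs.
#'
#' @param path FASTA path.
#' @param ref A [reference_segment()].
#' @param batch_id Batch identifier stamped on all records.
#' @return Clone table.
#' @export
read_clone_fasta <- function(path, ref = synthetic_hvs1_reference(),
                             batch_id = NA_character_) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) stop("no FASTA records in ", path)
  out <- do.call(rbind, lapply(seq_along(hdr_idx), function(k) {
    i <- hdr_idx[k]
    j <- if (k < length(hdr_idx)) hdr_idx[k + 1] - 1L else length(lines)
    fields <- strsplit(sub("^>", "", lines[i]), "|", fixed = TRUE)[[1]]
    if (length(fields) != 5L) {
      stop("malformed clone FASTA header: ", lines[i])
    }
    seq <- paste(lines[(i + 1L):j], collapse = "")
    win <- .fragment_window(as.integer(fields[4]))
    if (nchar(seq) != win[2] - win[1] + 1L) {
      stop("sequence length does not match fragment window for ",
           fields[5])
    }
    # embed the fragment sequence into the full segment for variant calling
    full <- paste(ref$bases, collapse = "")
    substr(full, win[1] - ref$start + 1L, win[2] - ref$start + 1L) <- seq
    h <- variants_from_sequence(full, ref, window = win)
    data.frame(clone_id = fields[5], sample_id = fields[1],
               extraction_id = fields[2], pcr_id = fields[3],
               fragment_id = as.integer(fields[4]), batch_id = batch_id,
               motif = format_motif(h), origin = "unclassified")
  }))
  rownames(out) <- NULL
  as_clone_table(out)
}
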
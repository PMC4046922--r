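# Loader for the packaged PPNB typing fixture: 15 consensus profiles
# (HVS1 motif plus covered window), their coding-region SNP typings with
# replication flags, and the haplogroup printed for each skeleton.  H53 is
# marked provisional because its SNP typings were never replicated across
# extracts.

#' The packaged PPNB typing fixture
#'
#' Returns the 15 Near Eastern PPNB consensus profiles bundled with the
#' package: per skeleton the HVS1 motif over its covered window, the nine
#' coding-region SNP typings with their replication (`validated`) flags,
#' and the published haplogroup label.  Ten profiles cover the complete
#' window np 16,126-16,369; five are partial.
#'
#' @return A list with `profiles` (data frame: site, sample_id, motif,
#'   window_lo, window_hi, haplogroup, status), `snps` (data frame:
#'   sample_id, position, base, validated) and `haplotypes` (named list of
#'   [haplotype()] objects).
#' @export
ppnb_fixture <- function() {
  prof <- utils::read.delim(system.file("extdata", "ppnb_profiles.tsv",
                                        package = "paleomito"),
                            stringsAsFactors = FALSE,
                            na.strings = character(0))
  snps <- utils::read.delim(system.file("extdata", "ppnb_snp_typings.tsv",
                                        package = "paleomito"),
                            stringsAsFactors = FALSE,
                            na.strings = character(0))
  haps <- lapply(seq_len(nrow(prof)), function(i) {
    parse_motif(prof$motif[i],
                window = c(prof$window_lo[i], prof$window_hi[i]))
  })
  names(haps) <- prof$sample_id
  list(profiles = prof, snps = snps, haplotypes = haps)
}

#' Classify every profile of the packaged fixture
#'
#' Runs [classify_profile()] on the 15 fixture profiles using their SNP
#' typings and a decision table.
#'
#' @param table A [load_decision_table()] object.
#' @return Data frame with columns `sample_id`, `label`, `firm`, `basis`.
#' @export
classify_ppnb_fixture <- function(table = load_decision_table()) {
  fx <- ppnb_fixture()
  calls <- lapply(fx$profiles$sample_id, function(id) {
    s <- fx$snps[fx$snps$sample_id == id, c("position", "base", "validated")]
    classify_profile(fx$haplotypes[[id]], s, table)
  })
  data.frame(sample_id = fx$profiles$sample_id,
             label = vapply(calls, `[[`, "", "label"),
             firm = vapply(calls, `[[`, TRUE, "firm"),
             basis = vapply(calls, `[[`, "", "basis"))
}
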
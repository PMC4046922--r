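# End-to-end orchestration and run configuration.  The package's R
# functions are the command surface; run_pipeline() chains the packaged
# fixture through classification, frequency tabulation, haplotype
# deduplication and (optionally) comparison against a simulated database,
# writing plain-text outputs plus a JSON manifest sufficient to re-run
# the analysis bit-identically.

.run_defaults <- function() {
  list(n_permutations = 10000L, bootstrap_B = 1000L, pca_components = 6L,
       k_clusters = 6L, idw_power = 2, seed = 1L, log_level = "info")
}

#' Load a run configuration
#'
#' Reads a JSON configuration file, fills defaults (10,000 permutations,
#' 1,000 bootstrap replicates, 6 principal components, 6 clusters, IDW
#' power 2) and rejects unknown keys and out-of-range values.
#'
#' @param path Path to a JSON file; `NULL` returns the defaults.
#' @return Named list of validated settings.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- .run_defaults()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  stopifnot(cfg$n_permutations >= 100L, cfg$bootstrap_B >= 100L,
            cfg$pca_components >= 1L, cfg$k_clusters >= 1L,
            cfg$idw_power > 0)
  cfg
}

#' Run the fixture-to-report pipeline
#'
#' Classifies the packaged 15-profile fixture, tabulates firm-call
#' haplogroup frequencies with bootstrap intervals, deduplicates
#' haplotypes, and - when `compare = TRUE` - simulates a database and
#' computes shared-haplotype statistics and permutation-tested FST
#' against it.  Every output lands in `out_dir` along with a
#' `manifest.json` recording inputs, parameters and the seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing every stochastic step.
#' @param n_permutations Permutations per FST test (default 1,000 here;
#'   raise to 10,000 for production runs).
#' @param bootstrap_B Bootstrap replicates for frequency intervals.
#' @param compare Also run the population-comparison stage against a
#'   simulated database (default `TRUE`).
#' @return Invisibly, a list with the main results (calls, frequencies,
#'   dedup counts, comparison tables).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_permutations = 1000L,
                         bootstrap_B = 1000L, compare = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- ppnb_fixture()
  calls <- classify_ppnb_fixture()
  utils::write.csv(calls, file.path(out_dir, "haplogroup_calls.csv"),
                   row.names = FALSE)
  dd_all <- distinct_haplotypes(fx$haplotypes)
  dd_complete <- distinct_haplotypes(fx$haplotypes, complete_only = TRUE)
  freq <- haplogroup_frequencies(calls$label, firm = calls$firm,
                                 grouping = NULL)
  utils::write.csv(freq, file.path(out_dir, "haplogroup_frequencies.csv"),
                   row.names = FALSE)
  ci <- bootstrap_ci(calls$label[calls$firm], B = bootstrap_B,
                     seed = seed + 10L)
  utils::write.csv(ci, file.path(out_dir, "frequency_bootstrap_ci.csv"),
                   row.names = FALSE)
  comparison <- NULL
  if (compare) {
    cfg <- simulation_config(n_populations = 5L, n_per_pop = 40L,
                             seed = seed + 20L)
    sim <- simulate_database(cfg)
    shared <- shared_haplotypes(fx$profiles, sim$db,
                                require_haplogroup = FALSE)
    utils::write.csv(shared, file.path(out_dir, "shared_haplotypes.csv"),
                     row.names = FALSE)
    qkeys <- vapply(which(fx$profiles$window_lo <= hvs1_window()[1] &
                            fx$profiles$window_hi >= hvs1_window()[2]),
                    function(i) fx$profiles$motif[i], "")
    fst <- fst_scan(qkeys, sim$db, n_perm = n_permutations,
                    seed = seed + 30L)
    utils::write.csv(fst, file.path(out_dir, "fst_scan.csv"),
                     row.names = FALSE)
    comparison <- list(shared = shared, fst = fst)
  }
  manifest <- list(
    inputs = list(fixture = "ppnb_profiles.tsv (packaged)",
                  decision_table = "decision_table.tsv (packaged)"),
    parameters = list(seed = seed, n_permutations = n_permutations,
                      bootstrap_B = bootstrap_B, compare = compare),
    results = list(n_profiles = nrow(calls),
                   n_firm = sum(calls$firm),
                   n_distinct_haplotypes = dd_all$n_distinct,
                   n_distinct_complete = dd_complete$n_distinct),
    version = as.character(utils::packageVersion("paleomito")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("profiles: ", nrow(calls), "; firm haplogroup calls: ",
          sum(calls$firm), "; distinct haplotypes: ", dd_all$n_distinct)
  invisible(list(calls = calls, frequencies = freq, bootstrap = ci,
                 n_distinct = dd_all$n_distinct,
                 n_distinct_complete = dd_complete$n_distinct,
                 comparison = comparison, manifest = manifest))
}
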
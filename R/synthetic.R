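# Synthetic-data generator: populations with Dirichlet haplogroup
# frequencies and star-phylogeny haplotype diversity, clone experiments
# with miscoding lesions and planted contamination, and staff panels -
# everything with recorded ground truth so estimator recovery can be
# tested end to end.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults mirror the laboratory design the pipeline targets: 10-15
#' clones per amplicon, two independent extractions per skeleton with two
#' PCRs each, and a per-site miscoding-lesion probability of 0.005 per
#' clone dominated by type 2 (deamination-driven) changes - the middle of
#' the per-sample range ancient control-region data typically shows.
#'
#' @param n_populations Number of populations in the simulated database.
#' @param n_per_pop Individuals per population (scalar or vector).
#' @param n_haplogroups Number of founder haplogroups.
#' @param dirichlet_concentration Dirichlet concentration per haplogroup
#'   category (scalar or vector of length `n_haplogroups`).
#' @param mu Mean number of private mutations per lineage (star
#'   phylogeny: founder motif plus Poisson(`mu`) private variants).
#' @param transition_fraction Fraction of simulated mutations that are
#'   transitions (default 0.9, typical control-region behaviour).
#' @param lambda Per-site, per-clone miscoding-lesion probability.
#' @param type2_fraction Fraction of lesions that are type 2 (C->T/G->A).
#' @param contaminant_fraction Fraction of clones copied from a staff
#'   motif.
#' @param carryover_fraction Fraction of clones copied from a batch
#'   neighbour.
#' @param clones_range Integer `c(min, max)` clones per amplicon, within
#'   `[1, 50]`.
#' @param n_extracts Extractions per sample (default 2).
#' @param n_pcrs PCRs per extraction (default 2).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_populations = 6L, n_per_pop = 50L,
                              n_haplogroups = 8L,
                              dirichlet_concentration = 1,
                              mu = 0.8, transition_fraction = 0.9,
                              lambda = 0.005, type2_fraction = 0.85,
                              contaminant_fraction = 0.1,
                              carryover_fraction = 0.05,
                              clones_range = c(10L, 15L),
                              n_extracts = 2L, n_pcrs = 2L, seed) {
  if (missing(seed)) stop("`seed` is required")
  rates <- c(transition_fraction = transition_fraction, lambda = lambda,
             type2_fraction = type2_fraction,
             contaminant_fraction = contaminant_fraction,
             carryover_fraction = carryover_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("rate parameter outside [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  clones_range <- as.integer(clones_range)
  if (length(clones_range) != 2L || clones_range[1] > clones_range[2] ||
      clones_range[1] < 1L || clones_range[2] > 50L) {
    stop("`clones_range` must be c(min, max) within [1, 50]")
  }
  stopifnot(n_populations >= 1L, all(n_per_pop >= 1L),
            n_haplogroups >= 1L, mu >= 0,
            all(dirichlet_concentration > 0),
            n_extracts >= 1L, n_pcrs >= 1L)
  structure(list(n_populations = as.integer(n_populations),
                 n_per_pop = as.integer(n_per_pop),
                 n_haplogroups = as.integer(n_haplogroups),
                 dirichlet_concentration = dirichlet_concentration,
                 mu = mu, transition_fraction = transition_fraction,
                 lambda = lambda, type2_fraction = type2_fraction,
                 contaminant_fraction = contaminant_fraction,
                 carryover_fraction = carryover_fraction,
                 clones_range = clones_range,
                 n_extracts = as.integer(n_extracts),
                 n_pcrs = as.integer(n_pcrs),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# transition partner of a base
.transition <- c(A = "G", G = "A", C = "T", T = "C")

# mutate `state` at position index i (transition-biased)
.mutate_base <- function(base, transition_fraction) {
  if (stats::runif(1) < transition_fraction) {
    .transition[[base]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"),
                   c(base, .transition[[base]])), 1L)
  }
}

# random motif: founder variants at distinct scored positions
.random_motif <- function(n_var, ref, window = hvs1_window(),
                          transition_fraction = 0.9,
                          exclude_positions = integer(0)) {
  pos_pool <- setdiff(seq.int(window[1], window[2]),
                      c(excluded_positions(ref), exclude_positions))
  pos <- sort(sample(pos_pool, n_var))
  bases <- vapply(ref_base(ref, pos), .mutate_base, "",
                  transition_fraction = transition_fraction)
  haplotype(pos, unname(bases), window = window)
}

#' Simulate a multi-population haplotype database
#'
#' Per population, haplogroup counts are multinomial over a Dirichlet
#' draw; each individual carries its haplogroup's founder motif plus a
#' Poisson(`mu`) number of private transition-biased variants (star
#' phylogeny).  Fully reproducible given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param ref A [reference_segment()].
#' @return List with `db` (data frame: individual_id, population, motif,
#'   haplogroup), `populations` (population, lat, lon, geographic_ok),
#'   `truth` (founder motifs per haplogroup and the Dirichlet frequency
#'   draws).
#' @export
simulate_database <- function(cfg, ref = synthetic_hvs1_reference()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n_hg <- cfg$n_haplogroups
  hg_labels <- sprintf("HG%02d", seq_len(n_hg))
  founders <- list(); used_pos <- integer(0)
  for (i in seq_len(n_hg)) {
    f <- .random_motif(sample(1:3, 1L), ref,
                       transition_fraction = cfg$transition_fraction,
                       exclude_positions = used_pos)
    used_pos <- c(used_pos, f$positions)
    founders[[hg_labels[i]]] <- f
  }
  conc <- rep_len(cfg$dirichlet_concentration, n_hg)
  sizes <- rep_len(cfg$n_per_pop, cfg$n_populations)
  if (any(sizes < 1L)) stop("zero sample size")
  freqs <- matrix(NA_real_, cfg$n_populations, n_hg,
                  dimnames = list(NULL, hg_labels))
  rows <- vector("list", cfg$n_populations)
  for (p in seq_len(cfg$n_populations)) {
    g <- stats::rgamma(n_hg, shape = conc)
    pi <- g / sum(g)
    freqs[p, ] <- pi
    counts <- as.integer(stats::rmultinom(1, sizes[p], pi))
    hgs <- rep(hg_labels, counts)
    motifs <- vapply(hgs, function(hg) {
      f <- founders[[hg]]
      k <- stats::rpois(1, cfg$mu)
      if (k > 0) {
        pool <- setdiff(seq.int(f$window[1], f$window[2]),
                        c(excluded_positions(ref), f$positions))
        pos <- sample(pool, min(k, length(pool)))
        bases <- vapply(ref_base(ref, pos), .mutate_base, "",
                        transition_fraction = cfg$transition_fraction)
        f <- haplotype(c(f$positions, pos), c(f$bases, unname(bases)),
                       window = f$window)
      }
      format_motif(f)
    }, "", USE.NAMES = FALSE)
    rows[[p]] <- data.frame(
      individual_id = sprintf("P%02d-%04d", p, seq_along(hgs)),
      population = sprintf("pop%02d", p),
      motif = motifs, haplogroup = hgs)
  }
  db <- do.call(rbind, rows)
  pops <- data.frame(population = sprintf("pop%02d",
                                          seq_len(cfg$n_populations)),
                     lat = stats::runif(cfg$n_populations, 30, 55),
                     lon = stats::runif(cfg$n_populations, -10, 60),
                     geographic_ok = TRUE)
  list(db = db, populations = pops,
       truth = list(founders = lapply(founders, format_motif),
                    frequencies = freqs))
}

#' Simulate a staff panel
#'
#' Generates distinct random HVS1 motifs for the laboratory and field
#' staff, disjoint from a supplied set of sample motifs unless a
#' collision is explicitly requested.
#'
#' @param n_people Number of handlers (>= 1).
#' @param cfg A [simulation_config()] (transition bias and seed).
#' @param avoid_motifs Character vector of motifs the panel must not
#'   contain.
#' @param collide_with Optional motif to include verbatim (flagged in the
#'   output), emulating a handler sharing a sample's haplotype.
#' @param ref A [reference_segment()].
#' @return Data frame `person_id`, `motif`, `collision`.
#' @export
simulate_staff_panel <- function(n_people, cfg,
                                 avoid_motifs = character(0),
                                 collide_with = NULL,
                                 ref = synthetic_hvs1_reference()) {
  stopifnot(n_people >= 1L, inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  motifs <- character(0)
  while (length(motifs) < n_people) {
    m <- format_motif(.random_motif(sample(2:4, 1L), ref,
                      transition_fraction = cfg$transition_fraction))
    if (!(m %in% c(motifs, avoid_motifs))) motifs <- c(motifs, m)
  }
  collision <- rep(FALSE, n_people)
  if (!is.null(collide_with)) {
    motifs[n_people] <- collide_with
    collision[n_people] <- TRUE
  }
  data.frame(person_id = sprintf("staff%02d", seq_len(n_people)),
             motif = motifs, collision = collision)
}

#' Simulate one sample's clone experiment
#'
#' Emulates the cloning design: for every extraction x PCR x fragment
#' amplicon, a uniform number of clones in `cfg$clones_range` is drawn;
#' each endogenous clone receives Bernoulli(`lambda`) miscoding lesions
#' per scored site (type 2 with probability `type2_fraction`, type 1
#' otherwise); clones are replaced by staff or batch-neighbour motifs at
#' the configured fractions.  True origin labels and planted lesion
#' positions are recorded.
#'
#' @param truth_motif The sample's true HVS1 motif (complete window).
#' @param cfg A [simulation_config()].
#' @param staff Staff panel data frame (`person_id`, `motif`) or `NULL`.
#' @param neighbor_motifs Character vector of same-batch neighbour motifs
#'   (carry-over sources), possibly empty.
#' @param sample_id,batch_id Identifiers stamped on the clone records.
#' @param seed Seed; defaults to `cfg$seed`.
#' @param ref A [reference_segment()].
#' @return List with `clones` (clone table with `origin` unclassified),
#'   `truth` (clone_id, true_origin, n_lesions) and `lesions` (clone_id,
#'   position, type).
#' @export
simulate_clone_experiment <- function(truth_motif, cfg, staff = NULL,
                                      neighbor_motifs = character(0),
                                      sample_id = "S1", batch_id = "B1",
                                      seed = cfg$seed,
                                      ref = synthetic_hvs1_reference()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  truth_h <- parse_motif(truth_motif, window = hvs1_window())
  staff_motifs <- if (!is.null(staff)) staff$motif else character(0)
  fr <- amplicon_fragments()
  clones <- NULL; truth <- NULL; lesions <- NULL
  clone_no <- 0L
  for (e in seq_len(cfg$n_extracts)) {
    for (pcr in seq_len(cfg$n_pcrs)) {
      for (f in fr$fragment_id) {
        win <- c(fr$lo[fr$fragment_id == f], fr$hi[fr$fragment_id == f])
        scored <- fragment_scored_positions(f, ref)
        truth_states <- .state_at(trim_to_window(truth_h, win), scored, ref)
        refb <- ref_base(ref, scored)
        n_clones <- sample(seq(cfg$clones_range[1], cfg$clones_range[2]),
                           1L)
        for (ci in seq_len(n_clones)) {
          clone_no <- clone_no + 1L
          cid <- sprintf("%s-E%d-P%d-F%d-C%02d", sample_id, e, pcr, f, ci)
          u <- stats::runif(1)
          origin <- "endogenous"
          if (length(staff_motifs) && u < cfg$contaminant_fraction) {
            origin <- "staff_contaminant"
          } else if (length(neighbor_motifs) &&
                     u < cfg$contaminant_fraction +
                         cfg$carryover_fraction) {
            origin <- "carry_over"
          }
          if (origin == "staff_contaminant") {
            src <- sample(staff_motifs, 1L)
            motif <- format_motif(trim_to_window(
              parse_motif(src, window = hvs1_window()), win))
            n_les <- 0L
          } else if (origin == "carry_over") {
            src <- sample(neighbor_motifs, 1L)
            motif <- format_motif(trim_to_window(
              parse_motif(src, window = hvs1_window()), win))
            n_les <- 0L
          } else {
            state <- truth_states
            n_les <- stats::rbinom(1, length(scored), cfg$lambda)
            if (n_les > 0) {
              for (l in seq_len(n_les)) {
                want2 <- stats::runif(1) < cfg$type2_fraction
                eligible <- if (want2) state %in% c("C", "G") else
                  state %in% c("A", "T")
                idx_pool <- which(eligible)
                if (!length(idx_pool)) idx_pool <- seq_along(state)
                i <- if (length(idx_pool) == 1L) idx_pool else
                  sample(idx_pool, 1L)
                newb <- .transition[[state[i]]]
                lesions <- rbind(lesions, data.frame(
                  clone_id = cid, position = scored[i],
                  type = substitution_type(state[i], newb)))
                state[i] <- newb
              }
            }
            var_idx <- which(state != refb)
            motif <- format_motif(haplotype(scored[var_idx],
                                            state[var_idx], window = win))
          }
          clones <- rbind(clones, data.frame(
            clone_id = cid, sample_id = sample_id,
            extraction_id = sprintf("%s-E%d", sample_id, e),
            pcr_id = sprintf("P%d", pcr), fragment_id = f,
            batch_id = batch_id, motif = motif,
            origin = "unclassified"))
          truth <- rbind(truth, data.frame(clone_id = cid,
                                           true_origin = origin,
                                           n_lesions = n_les))
        }
      }
    }
  }
  if (is.null(lesions)) {
    lesions <- data.frame(clone_id = character(0), position = integer(0),
                          type = character(0))
  }
  list(clones = clones, truth = truth, lesions = lesions)
}

#' Run the authentication pipeline on one simulated sample
#'
#' Convenience used by recovery studies: labels clone origins amplicon by
#' amplicon and calls the sample consensus.
#'
#' @param clones Clone table (e.g. from [simulate_clone_experiment()]).
#' @param staff,batch_neighbors Passed to [label_clone_origins()].
#' @param ref A [reference_segment()].
#' @return A `consensus_profile`.
#' @export
consensus_from_clones <- function(clones, staff = NULL,
                                  batch_neighbors = NULL,
                                  ref = synthetic_hvs1_reference()) {
  clones <- as_clone_table(clones)
  amp_key <- interaction(clones$extraction_id, clones$pcr_id,
                         clones$fragment_id, drop = TRUE)
  labelled <- do.call(rbind, lapply(split(clones, amp_key),
    label_clone_origins, staff = staff,
    batch_neighbors = batch_neighbors, ref = ref))
  call_sample_consensus(labelled, ref = ref)
}

#' Write the packaged fixture suite to a directory
#'
#' Materialises (1) the 15-profile typing fixture, (2) a small synthetic
#' multi-population database with its ground truth, and (3) one synthetic
#' clone experiment, all as plain-text tables, together with MD5 checksums
#' and a JSON manifest recording the seed.  Regeneration with the same
#' seed reproduces identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic components.
#' @return Invisibly, the manifest as a list.
#' @export
build_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  fx <- ppnb_fixture()
  utils::write.table(fx$profiles, file.path(out_dir, "ppnb_profiles.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fx$snps, file.path(out_dir, "ppnb_snp_typings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- simulation_config(n_populations = 4L, n_per_pop = 30L,
                           seed = seed)
  sim <- simulate_database(cfg)
  utils::write.csv(sim$db, file.path(out_dir, "synthetic_database.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$populations,
                   file.path(out_dir, "synthetic_populations.csv"),
                   row.names = FALSE)
  truth_freq <- as.data.frame(sim$truth$frequencies)
  truth_freq$population <- sim$populations$population
  utils::write.csv(truth_freq,
                   file.path(out_dir, "synthetic_truth_frequencies.csv"),
                   row.names = FALSE)
  staff <- simulate_staff_panel(7L, cfg)
  utils::write.table(staff, file.path(out_dir, "synthetic_staff.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  exp <- simulate_clone_experiment("16224C 16311C", cfg, staff = staff,
                                   sample_id = "SYN1", seed = seed + 2L)
  utils::write.table(exp$clones, file.path(out_dir,
                                           "synthetic_clones.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(exp$truth,
                     file.path(out_dir, "synthetic_clone_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("checksums|manifest", files)]
  sums <- tools::md5sum(files)
  utils::write.table(data.frame(file = basename(names(sums)),
                                md5 = unname(sums)),
                     file.path(out_dir, "checksums.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(seed = seed, n_files = length(files),
                   files = basename(names(sums)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
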
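# Decision-table haplogroup assignment from HVS1 motifs plus coding-region
# SNPs, with phylogenetic-consistency checking and frequency tabulation.
#
# The classifier is a small editable rule table, not an embedded
# phylogenetic tree: each rule names a haplogroup, the coding-region SNP
# alleles required for it (untyped positions are wildcards - ancient
# typings are routinely incomplete) and the HVS1 motif variants that
# characterise it.  Classification proceeds in two stages: rules whose SNP
# conditions conflict with a typed allele are eliminated, the remaining
# rules are ranked by the number of positively matched (typed and equal)
# SNP conditions, and motif conditions refine among SNP-tied rules.

#' The registered coding-region SNP panel
#'
#' @return Integer vector of the nine diagnostic coding-region positions.
#' @export
snp_panel <- function() {
  c(7028L, 12308L, 14766L, 10873L, 10550L, 12705L, 10398L, 10400L, 4646L)
}

# parse "7028T;12308G" -> data.frame(position, base)
.parse_conditions <- function(txt, line = NA) {
  txt <- trimws(txt)
  if (is.na(txt) || txt == "" || txt == ".") {
    return(data.frame(position = integer(0), base = character(0)))
  }
  tok <- trimws(strsplit(txt, "[;,]")[[1]])
  m <- regmatches(tok, regexec("^([0-9]+)([ACGTacgt])$", tok))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed condition token '", tok[bad][1], "'",
         if (!is.na(line)) paste0(" (line ", line, ")") else "")
  }
  data.frame(position = vapply(m, function(x) as.integer(x[2]), 1L),
             base = toupper(vapply(m, function(x) x[3], "")))
}

#' Load a haplogroup decision table
#'
#' Reads a TSV with columns `label`, `snp_conditions`, `motif_conditions`
#' and `priority`.  Conditions are `;`-separated `<position><base>` tokens;
#' an empty field or `.` means no condition of that kind.  Each rule must
#' have at least one condition; duplicate labels are rejected.
#'
#' @param path Path to the TSV; defaults to the decision table shipped with
#'   the package, which encodes the labels the nine-SNP panel plus HVS1
#'   motifs can distinguish (H, HV, HV0, R0, K, U*, N*, L3).
#' @return An object of class `decision_table`.
#' @export
load_decision_table <- function(path = system.file("extdata",
                                                   "decision_table.tsv",
                                                   package = "paleomito")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  req <- c("label", "snp_conditions", "motif_conditions", "priority")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("decision table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicate rule label: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  rules <- lapply(seq_len(nrow(tab)), function(i) {
    snp <- .parse_conditions(tab$snp_conditions[i], line = i + 1L)
    motif <- .parse_conditions(tab$motif_conditions[i], line = i + 1L)
    if (!nrow(snp) && !nrow(motif)) {
      stop("rule '", tab$label[i], "' has no conditions (line ", i + 1L, ")")
    }
    list(label = tab$label[i], snp = snp, motif = motif,
         priority = as.integer(tab$priority[i]))
  })
  structure(list(rules = rules), class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat("<decision_table> ", length(x$rules), " rules: ",
      paste(vapply(x$rules, `[[`, "", "label"), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# normalise SNP typings to data.frame(position, base, validated)
.as_snp_typing <- function(s) {
  empty <- data.frame(position = integer(0), base = character(0),
                      validated = logical(0))
  if (is.null(s)) return(empty)
  s <- as.data.frame(s)
  if (!nrow(s)) return(empty)
  stopifnot(all(c("position", "base") %in% names(s)))
  if (is.null(s$validated)) s$validated <- FALSE
  s$position <- as.integer(s$position)
  s$base <- toupper(as.character(s$base))
  panel <- snp_panel()
  if (!all(s$position %in% panel)) {
    stop("SNP typing at unregistered position: ",
         paste(setdiff(s$position, panel), collapse = ", "))
  }
  s[c("position", "base", "validated")]
}

# core rule matching; returns winning rule index or NA, plus diagnostics
.match_rules <- function(h, snps, table) {
  rules <- table$rules
  n <- length(rules)
  conflict <- logical(n); positives <- integer(n)
  motif_sat <- integer(n); motif_violated <- logical(n)
  motif_n <- integer(n)
  for (i in seq_len(n)) {
    r <- rules[[i]]
    if (nrow(r$snp)) {
      idx <- match(r$snp$position, snps$position)
      typed <- !is.na(idx)
      eq <- typed & snps$base[idx] == r$snp$base
      conflict[i] <- any(typed & !eq)
      positives[i] <- sum(eq)
    }
    motif_n[i] <- nrow(r$motif)
    if (nrow(r$motif)) {
      covered <- r$motif$position >= h$window[1] &
        r$motif$position <= h$window[2]
      idx <- match(r$motif$position, h$positions)
      present <- !is.na(idx) & h$bases[ifelse(is.na(idx), 1L, idx)] ==
        r$motif$base
      motif_sat[i] <- sum(present)
      # a required variant whose position is covered but absent (or
      # different) violates the condition; uncovered positions are wildcards
      motif_violated[i] <- any(covered & !present)
    }
  }
  cand <- which(!conflict)
  if (!length(cand)) {
    return(list(winner = NA_integer_, positives = positives,
                motif_sat = motif_sat, conflict = conflict))
  }
  top <- cand[positives[cand] == max(positives[cand])]
  # unassigned when nothing positively supports any rule
  if (max(positives[top]) == 0L && max(motif_sat[top]) == 0L) {
    return(list(winner = NA_integer_, positives = positives,
                motif_sat = motif_sat, conflict = conflict))
  }
  # motif refinement among SNP-tied rules
  if (length(top) > 1L && any(!motif_violated[top])) {
    top <- top[!motif_violated[top]]
  }
  if (length(top) > 1L) {
    top <- top[motif_sat[top] == max(motif_sat[top])]
  }
  if (length(top) > 1L) {
    pr <- vapply(rules[top], `[[`, 1L, "priority")
    top <- top[pr == min(pr)]
  }
  list(winner = top[1], positives = positives, motif_sat = motif_sat,
       conflict = conflict)
}

#' Classify a profile into a haplogroup
#'
#' Assigns a haplogroup from an HVS1 haplotype and coding-region SNP
#' typings using a decision table.  Rules conflicting with a typed SNP are
#' eliminated; among the rest the rule with the most positively matched SNP
#' conditions wins, with motif conditions (evaluated over the haplotype's
#' covered window; uncovered positions are wildcards) refining ties and
#' rule priority breaking what remains.  A call is *firm* unless it rests
#' solely on unvalidated SNP typings, i.e. unless reclassification using
#' validated typings only changes the label.
#'
#' @param h A [haplotype()] (HVS1 motif with covered window).
#' @param snps SNP typings: data frame `position`, `base`, optional
#'   `validated`; may be `NULL` or empty.
#' @param table A [load_decision_table()] object.
#' @return An object of class `haplogroup_call` with fields `label`
#'   (`NA` when unassigned), `basis` (`"snp"`, `"motif"` or `"both"`),
#'   `firm`, and `consistency` placeholder (see [consistency_check()]).
#' @export
classify_profile <- function(h, snps = NULL,
                             table = load_decision_table()) {
  stopifnot(inherits(h, "mito_haplotype"), inherits(table, "decision_table"))
  snps <- .as_snp_typing(snps)
  res <- .match_rules(h, snps, table)
  if (is.na(res$winner)) {
    return(structure(list(label = NA_character_, basis = NA_character_,
                          firm = FALSE, consistency = "untestable",
                          rule = NULL),
                     class = "haplogroup_call"))
  }
  w <- res$winner
  basis <- if (res$positives[w] > 0L && res$motif_sat[w] > 0L) "both"
           else if (res$positives[w] > 0L) "snp" else "motif"
  # firmness: does the decision survive on validated evidence alone?
  res_val <- .match_rules(h, snps[snps$validated, , drop = FALSE], table)
  firm <- !is.na(res_val$winner) &&
    table$rules[[res_val$winner]]$label == table$rules[[w]]$label
  structure(list(label = table$rules[[w]]$label, basis = basis,
                 firm = firm, consistency = NA_character_,
                 rule = table$rules[[w]]),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat("<haplogroup_call> ",
      if (is.na(x$label)) "unassigned" else x$label,
      if (isTRUE(x$firm)) " (firm)" else " (provisional)",
      if (!is.na(x$basis)) paste0("  basis: ", x$basis) else "",
      "\n", sep = "")
  invisible(x)
}

#' Phylogenetic-consistency check of motif and SNP evidence
#'
#' Compares the haplogroup candidates implied by the HVS1 motif alone
#' (rules whose motif conditions are fully satisfied) with those implied by
#' the SNP typings alone (rules with at least one positively matched SNP
#' and no conflict).  Disjoint non-empty candidate sets flag a conflict;
#' an empty side makes the check untestable.
#'
#' @param h A [haplotype()].
#' @param snps SNP typings as in [classify_profile()].
#' @param call The [classify_profile()] result (must be assigned).
#' @param table The decision table used for the call.
#' @return List with `consistency` (`"consistent"`, `"conflict"`,
#'   `"untestable"`), `motif_candidates`, `snp_candidates`, `reasons`.
#' @export
consistency_check <- function(h, snps, call, table = load_decision_table()) {
  stopifnot(inherits(call, "haplogroup_call"))
  if (is.na(call$label)) stop("consistency_check() requires an assigned call")
  snps <- .as_snp_typing(snps)
  labels <- vapply(table$rules, `[[`, "", "label")
  motif_cand <- character(0); snp_cand <- character(0)
  for (i in seq_along(table$rules)) {
    r <- table$rules[[i]]
    if (nrow(r$motif)) {
      idx <- match(r$motif$position, h$positions)
      present <- !is.na(idx) & h$bases[ifelse(is.na(idx), 1L, idx)] ==
        r$motif$base
      if (all(present)) motif_cand <- c(motif_cand, r$label)
    }
    if (nrow(r$snp) && nrow(snps)) {
      idx <- match(r$snp$position, snps$position)
      typed <- !is.na(idx)
      eq <- typed & snps$base[idx] == r$snp$base
      if (!any(typed & !eq) && sum(eq) > 0L) {
        snp_cand <- c(snp_cand, r$label)
      }
    }
  }
  if (!length(motif_cand) || !length(snp_cand)) {
    cons <- "untestable"
    reasons <- "motif or SNP evidence alone implies no candidate"
  } else if (length(intersect(motif_cand, snp_cand))) {
    cons <- "consistent"
    reasons <- character(0)
  } else {
    cons <- "conflict"
    reasons <- paste0("motif-implied {",
                      paste(motif_cand, collapse = ","),
                      "} disjoint from SNP-implied {",
                      paste(snp_cand, collapse = ","), "}")
  }
  list(consistency = cons, motif_candidates = motif_cand,
       snp_candidates = snp_cand, reasons = reasons)
}

#' Load a haplogroup pooling scheme
#'
#' Reads a TSV mapping raw haplogroup labels to the pooled frequency
#' categories used in the population analyses.
#'
#' @param path TSV with columns `raw_label`, `category`; defaults to the
#'   scheme shipped with the package (25 categories: the common West
#'   Eurasian haplogroups plus pooled African `AF`, Asian `AS`, rare-`U`
#'   `U+` and rare-`R` `R+` bins).
#' @return Named character vector mapping raw label to category.
#' @export
load_grouping_scheme <- function(path = system.file(
                                   "extdata", "haplogroup_grouping.tsv",
                                   package = "paleomito")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  stopifnot(all(c("raw_label", "category") %in% names(tab)))
  stats::setNames(tab$category, tab$raw_label)
}

#' Haplogroup frequency table
#'
#' Tabulates absolute and relative pooled-category frequencies per
#' population.  The denominator is the number of firm calls; relative
#' frequencies therefore sum to 100 per population.  A label with no
#' grouping entry is an error, never silently dropped.
#'
#' @param labels Character vector of raw haplogroup labels (`NA` =
#'   unassigned, excluded).
#' @param population Population identifier per record (recycled if length
#'   1).
#' @param firm Logical vector: is the call firm?  Defaults to all `TRUE`.
#' @param grouping Named vector from [load_grouping_scheme()], or `NULL`
#'   to tabulate raw labels directly.
#' @return Data frame with columns `population`, `category`, `n`, `pct`.
#' @export
haplogroup_frequencies <- function(labels, population = "pop",
                                   firm = NULL, grouping =
                                     load_grouping_scheme()) {
  labels <- as.character(labels)
  if (length(population) == 1L) population <- rep(population, length(labels))
  stopifnot(length(population) == length(labels))
  if (is.null(firm)) firm <- rep(TRUE, length(labels))
  keep <- firm & !is.na(labels)
  labels <- labels[keep]; population <- population[keep]
  if (!is.null(grouping)) {
    unmapped <- setdiff(unique(labels), names(grouping))
    if (length(unmapped)) {
      stop("haplogroup label(s) with no grouping entry: ",
           paste(unmapped, collapse = ", "))
    }
    labels <- unname(grouping[labels])
  }
  out <- do.call(rbind, lapply(split(labels, population), function(l) {
    tab <- table(l)
    data.frame(category = names(tab), n = as.integer(tab),
               pct = 100 * as.integer(tab) / length(l))
  }))
  out$population <- sub("\\.[0-9]+$", "", rownames(out))
  rownames(out) <- NULL
  out[c("population", "category", "n", "pct")]
}

#' Population-by-category frequency matrix
#'
#' Reshapes a long frequency table into the populations x categories
#' percentage matrix consumed by [pca_haplogroups()].
#'
#' @param freq Output of [haplogroup_frequencies()].
#' @param categories Column order; defaults to the categories present.
#' @return Numeric matrix (rows = populations, columns = categories,
#'   entries = percent).
#' @export
frequency_matrix <- function(freq, categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(freq$category))
  pops <- unique(freq$population)
  m <- matrix(0, length(pops), length(categories),
              dimnames = list(pops, categories))
  idx <- cbind(match(freq$population, pops),
               match(freq$category, categories))
  ok <- !is.na(idx[, 2])
  if (any(!ok)) {
    stop("category absent from requested column set: ",
         paste(unique(freq$category[!ok]), collapse = ", "))
  }
  m[idx] <- freq$pct
  m
}

#' Bootstrap confidence intervals for haplogroup frequencies
#'
#' Non-parametric bootstrap with replacement over individuals of one
#' population: percentile intervals of each category's relative frequency.
#'
#' @param labels Character vector of (pooled) category labels, one per
#'   individual of the population.
#' @param B Number of bootstrap replicates (>= 100).
#' @param level Confidence level, default 0.95.
#' @param seed Mandatory integer seed.
#' @return Data frame with columns `category`, `pct`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(labels, B = 1000L, level = 0.95, seed) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty population")
  stopifnot(B >= 100L, level > 0, level < 1)
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  cats <- sort(unique(labels))
  n <- length(labels)
  reps <- matrix(0, B, length(cats), dimnames = list(NULL, cats))
  for (b in seq_len(B)) {
    res <- sample(labels, n, replace = TRUE)
    tab <- table(factor(res, levels = cats))
    reps[b, ] <- 100 * as.integer(tab) / n
  }
  alpha <- (1 - level) / 2
  est <- 100 * as.integer(table(factor(labels, levels = cats))) / n
  data.frame(category = cats, pct = est,
             lower = apply(reps, 2, stats::quantile, probs = alpha),
             upper = apply(reps, 2, stats::quantile, probs = 1 - alpha),
             row.names = NULL)
}
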
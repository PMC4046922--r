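# PCA of pooled haplogroup frequencies, Ward hierarchical clustering on
# the leading principal components, and cluster characterisation by test
# values (standardised deviation of cluster means with finite-population
# correction).

#' PCA of haplogroup frequency profiles
#'
#' Centred (and by default unit-variance standardised, i.e. correlation
#' mode) principal component analysis of a populations x categories
#' percentage matrix.  Zero-variance variables are dropped with a warning
#' under standardisation.  Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param freq Numeric matrix, rows = populations (>= 3), columns =
#'   frequency categories; no missing cells.
#' @param standardize Unit-variance standardisation (default `TRUE`).
#' @return An object of class `hg_pca`: `scores`, `loadings`,
#'   `eigenvalues`, `percent_variance` (sums to 100), `center`, `scale`,
#'   `variables`.
#' @export
pca_haplogroups <- function(freq, standardize = TRUE) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 3L) stop("PCA needs at least 3 populations")
  if (anyNA(freq)) stop("frequency matrix contains missing cells")
  if (standardize) {
    v <- apply(freq, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(freq)[v == 0], collapse = ", "))
      freq <- freq[, v > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(freq, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  eig <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation, eigenvalues = eig,
                 percent_variance = 100 * eig / sum(eig),
                 center = p$center,
                 scale = if (standardize) p$scale else NULL,
                 variables = colnames(freq)),
            class = "hg_pca")
}

#' @export
print.hg_pca <- function(x, ...) {
  k <- min(6L, length(x$percent_variance))
  cat("<hg_pca> ", nrow(x$scores), " populations x ",
      length(x$variables), " variables\n  % variance (first ", k, "): ",
      paste(sprintf("%.2f", x$percent_variance[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# inertia decomposition of a labelled score matrix
.inertia <- function(x, labels) {
  centre <- colMeans(x)
  total <- sum(sweep(x, 2, centre)^2)
  within <- sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xc <- x[idx, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, 0))
  c(total = total, within = within, between = total - within)
}

#' Ward clustering of PCA scores
#'
#' Agglomerative hierarchical clustering (Ward minimum-variance criterion,
#' Euclidean distances) of the first `n_components` principal component
#' scores.  The partition at `k` clusters is reported together with the
#' inertia decomposition (between-cluster, within-cluster, and the
#' between/total ratio) for every cut up to `max_k`.
#'
#' @param pca A [pca_haplogroups()] result (or a plain score matrix).
#' @param n_components Number of leading components clustered (default 6).
#' @param k Number of clusters to cut at.
#' @param max_k Largest cut for the inertia-ratio profile (default
#'   `min(12, n populations)`).
#' @return An object of class `cluster_partition`: `tree` (hclust),
#'   `k`, `labels`, `inertia` (total/within/between at `k`),
#'   `inertia_ratio`, `ratio_profile` (data frame k, ratio), `scores`.
#' @export
ward_partition <- function(pca, n_components = 6L, k, max_k = NULL) {
  scores <- if (inherits(pca, "hg_pca")) pca$scores else as.matrix(pca)
  n_components <- min(n_components, ncol(scores))
  x <- scores[, seq_len(n_components), drop = FALSE]
  n <- nrow(x)
  if (missing(k) || k < 1L || k > n) {
    stop("`k` must lie between 1 and the number of populations (", n, ")")
  }
  if (is.null(max_k)) max_k <- min(12L, n)
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  dec <- .inertia(x, labels)
  profile <- do.call(rbind, lapply(seq_len(max_k), function(kk) {
    d <- .inertia(x, stats::cutree(tree, k = kk))
    data.frame(k = kk, ratio = if (d["total"] > 0)
      unname(d["between"] / d["total"]) else 1)
  }))
  structure(list(tree = tree, k = k, labels = labels,
                 inertia = dec,
                 inertia_ratio = if (dec["total"] > 0)
                   unname(dec["between"] / dec["total"]) else 1,
                 ratio_profile = profile, scores = x),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> k = ", x$k, ", inertia ratio = ",
      sprintf("%.3f", x$inertia_ratio), "\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Test values and significance marks per cluster and variable
#'
#' For each cluster and frequency category, the test value is the
#' standardised deviation of the cluster mean from the overall mean with
#' finite-population correction,
#' `v = (xbar_c - xbar) / sqrt(((N - n) / (N - 1)) * s2 / n)`,
#' where `s2` is the overall (population, denominator `N`) variance,
#' `N` the number of populations and `n` the cluster size; a two-sided
#' normal p-value accompanies each `v`.  Separately, a per-variable
#' one-sample t-test of the cluster's values against the overall mean
#' marks significantly higher/lower frequencies at `alpha`.
#'
#' @param partition A [ward_partition()] result or a label vector.
#' @param freq Populations x categories frequency matrix (same row order
#'   as the clustered scores).
#' @param alpha Significance level for the t-test marks (default 0.05).
#' @return Data frame with columns `cluster`, `variable`, `cluster_mean`,
#'   `overall_mean`, `test_value`, `p_value`, `mark` (`"+"`, `"-"` or
#'   `""`).
#' @export
test_values <- function(partition, freq, alpha = 0.05) {
  labels <- if (inherits(partition, "cluster_partition"))
    partition$labels else partition
  freq <- as.matrix(freq)
  if (length(labels) != nrow(freq)) {
    stop("labels do not cover all populations")
  }
  N <- nrow(freq)
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n == 0L) stop("cluster of size 0")
    do.call(rbind, lapply(seq_len(ncol(freq)), function(j) {
      x <- freq[, j]
      m_all <- mean(x); s2 <- sum((x - m_all)^2) / N
      m_cl <- mean(x[idx])
      v <- if (n == N || s2 == 0) 0 else
        (m_cl - m_all) / sqrt(((N - n) / (N - 1)) * s2 / n)
      p <- 2 * stats::pnorm(-abs(v))
      mark <- ""
      if (n >= 2L && stats::sd(x[idx]) > 0) {
        tt <- stats::t.test(x[idx], mu = m_all)
        if (tt$p.value < alpha) mark <- if (m_cl > m_all) "+" else "-"
      }
      data.frame(cluster = cl, variable = colnames(freq)[j],
                 cluster_mean = m_cl, overall_mean = m_all,
                 test_value = v, p_value = p, mark = mark)
    }))
  }))
  rownames(out) <- NULL
  out
}
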
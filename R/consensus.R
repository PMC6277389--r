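#' Consensus clustering of Pheno-Prints with bootstrap resampling
#'
#' For each resampling iteration, a random subset of compounds is drawn
#' without replacement (default 80%) and clustered by agglomerative
#' hierarchical clustering (Euclidean distance, average linkage); the tree is
#' cut at every candidate `k`. The consensus matrix entry for a compound pair
#' is the fraction of iterations in which the pair co-clustered among those
#' in which it was co-sampled. Pairs never co-sampled get consensus 0 with a
#' warning. For each `k` the area under the empirical CDF of the consensus
#' entries (upper triangle, trapezoidal rule on \[0, 1\]) is recorded for
#' cluster-number selection.
#'
#' @param phenoprints `n x d` matrix, rows named by compound id.
#' @param k_range candidate cluster counts, within `[2, n - 1]`.
#' @param n_iterations resampling iterations (default 1000).
#' @param subsample_frac fraction of compounds per iteration, in `(0, 1]`.
#' @param seed integer seed.
#' @param linkage hierarchical linkage method (default `"average"`).
#' @param replace sample compounds with replacement instead (classical
#'   bootstrap); duplicated rows are collapsed before clustering.
#' @return A list of class `consensus_result`: `M` (list of consensus
#'   matrices named by `k`), `cosampled` (pair co-sampling counts), `auc`
#'   (named numeric), `k_range`, and the resampling parameters.
#' @export
consensus_cluster <- function(phenoprints, k_range = 2:15,
                              n_iterations = 1000L, subsample_frac = 0.8,
                              seed = 1L, linkage = "average",
                              replace = FALSE) {
  x <- as.matrix(phenoprints)
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("item_%03d", seq_len(n))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop("`k_range` must lie within [2, n - 1]", call. = FALSE)
  }
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("`subsample_frac` must lie in (0, 1]", call. = FALSE)
  }
  m_sub <- ceiling(subsample_frac * n)
  if (max(k_range) >= m_sub) {
    stop("largest k (", max(k_range), ") must be below the subsample size (",
         m_sub, ")", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))

  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  cosamp <- matrix(0, n, n)

  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      idx <- if (replace) {
        unique(sample.int(n, m_sub, replace = TRUE))
      } else {
        sample.int(n, m_sub)
      }
      hc <- stats::hclust(stats::dist(x[idx, , drop = FALSE]), method = linkage)
      cosamp[idx, idx] <- cosamp[idx, idx] + 1
      for (k in k_range) {
        if (k >= length(idx)) next
        cl <- stats::cutree(hc, k = k)
        ind <- outer(cl, cl, `==`) * 1
        kk <- as.character(k)
        conn[[kk]][idx, idx] <- conn[[kk]][idx, idx] + ind
      }
    }
  })

  off <- upper.tri(cosamp)
  if (any(cosamp[off] == 0)) {
    warning("some compound pairs were never co-sampled; their consensus is 0")
  }
  M <- lapply(conn, function(cm) {
    m <- ifelse(cosamp > 0, cm / cosamp, 0)
    diag(m) <- 1
    dimnames(m) <- list(rownames(x), rownames(x))
    m
  })
  auc <- vapply(M, function(m) cdf_auc(m[upper.tri(m)]), 0)
  structure(list(M = M, cosampled = cosamp, auc = auc, k_range = k_range,
                 n_iterations = n_iterations, subsample_frac = subsample_frac,
                 seed = seed, linkage = linkage, replace = replace,
                 ids = rownames(x)),
            class = "consensus_result")
}

# Area under the empirical CDF of consensus entries over [0, 1],
# trapezoidal rule (diagonal excluded by the caller).
cdf_auc <- function(entries) {
  xs <- sort(unique(c(0, entries, 1)))
  Fx <- stats::ecdf(entries)(xs)
  sum(diff(xs) * (Fx[-length(Fx)] + Fx[-1L]) / 2)
}

#' Select the number of clusters by the AUC-CDF rule
#'
#' Returns the smallest candidate `k` from which onward the relative AUC
#' increase stays below the threshold (default 1%) for every subsequent step
#' in the candidate range: beyond the true cluster number, adding clusters no
#' longer substantially changes the consensus CDF.
#'
#' @param result a [consensus_cluster()] result, or a named numeric vector of
#'   AUC values indexed by consecutive `k`.
#' @param rel_increase_threshold relative-increase threshold (default 0.01).
#' @return The selected `k` (integer). If no candidate qualifies, the largest
#'   `k` is returned with a warning.
#' @export
select_k <- function(result, rel_increase_threshold = 0.01) {
  if (inherits(result, "consensus_result")) {
    auc <- result$auc
    ks <- result$k_range
  } else {
    auc <- result
    ks <- as.integer(names(auc))
    if (any(is.na(ks))) stop("AUC vector must be named by k", call. = FALSE)
  }
  if (length(ks) < 2L) stop("need AUC values for at least two k", call. = FALSE)
  if (any(diff(ks) != 1L)) stop("k values must be consecutive", call. = FALSE)
  rel <- diff(auc) / auc[-length(auc)]
  # below threshold from this step onward ("... and so on")
  below <- rev(cumprod(rev(rel < rel_increase_threshold))) > 0
  hit <- which(below)
  if (!length(hit)) {
    warning("no k satisfied the AUC-CDF rule; returning max(k_range)")
    return(ks[length(ks)])
  }
  ks[hit[1L]]
}

#' Cut final cluster labels from a consensus matrix
#'
#' Agglomerative clustering (average linkage) on the dissimilarity
#' `1 - M_k`, cut at `k`. Optionally computes each cluster's representative
#' pattern as the elementwise mean of in-cluster T-score BAMs.
#'
#' @param result a [consensus_cluster()] result.
#' @param k cluster count (must be in the result's `k_range`).
#' @param tscore_bams optional named list of T-score matrices for
#'   representative patterns.
#' @return A list of class `cluster_assignment`: `labels` (named integer
#'   vector, `1..k`), `k`, and `patterns` (list of mean maps, or `NULL`).
#' @export
cut_clusters <- function(result, k, tscore_bams = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  kk <- as.character(k)
  if (!kk %in% names(result$M)) {
    stop("no consensus matrix for k = ", k, call. = FALSE)
  }
  M <- result$M[[kk]]
  hc <- stats::hclust(stats::as.dist(1 - M), method = result$linkage)
  labels <- stats::cutree(hc, k = k)
  names(labels) <- result$ids
  patterns <- NULL
  if (!is.null(tscore_bams)) {
    patterns <- lapply(seq_len(k), function(cl) {
      members <- names(labels)[labels == cl]
      Reduce(`+`, tscore_bams[members]) / length(members)
    })
  }
  structure(list(labels = labels, k = k, patterns = patterns),
            class = "cluster_assignment")
}

#' Per-drug cluster-coherence tests
#'
#' For each drug, a one-tailed rank-sum (Mann-Whitney) test of whether its
#' consensus scores against in-cluster drugs are higher than against
#' out-of-cluster drugs, with Benjamini-Hochberg adjustment across drugs.
#' A distance-based variant on Pheno-Prints (in-cluster distances lower than
#' out-of-cluster) is reported alongside when `phenoprints` is supplied.
#' Singleton-cluster drugs get `NA` with a message.
#'
#' @param result a [consensus_cluster()] result (or a consensus matrix).
#' @param assignment a [cut_clusters()] result.
#' @param phenoprints optional `n x d` Pheno-Print matrix for the distance
#'   variant.
#' @return Data frame: `drug_id`, `cluster`, `p_consensus`, `q_consensus`,
#'   and (if requested) `p_distance`, `q_distance`.
#' @export
coherence_tests <- function(result, assignment, phenoprints = NULL) {
  labels <- assignment$labels
  M <- if (inherits(result, "consensus_result")) {
    result$M[[as.character(assignment$k)]]
  } else {
    result
  }
  stopifnot(identical(rownames(M), names(labels)))
  n <- length(labels)
  D <- if (!is.null(phenoprints)) {
    as.matrix(stats::dist(phenoprints[names(labels), , drop = FALSE]))
  } else {
    NULL
  }
  one_sided <- function(scores, in_idx, out_idx, alternative) {
    if (length(in_idx) < 1L || length(out_idx) < 1L) return(NA_real_)
    stats::wilcox.test(scores[in_idx], scores[out_idx],
                       alternative = alternative, exact = FALSE,
                       correct = TRUE)$p.value
  }
  p_cons <- p_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    in_idx <- setdiff(same, i)
    out_idx <- which(labels != labels[i])
    if (!length(in_idx)) {
      message("drug ", names(labels)[i], " is in a singleton cluster; ",
              "coherence p-value reported as NA")
      next
    }
    p_cons[i] <- one_sided(M[i, ], in_idx, out_idx, "greater")
    if (!is.null(D)) p_dist[i] <- one_sided(D[i, ], in_idx, out_idx, "less")
  }
  out <- data.frame(drug_id = names(labels), cluster = as.integer(labels),
                    p_consensus = p_cons,
                    q_consensus = stats::p.adjust(p_cons, method = "BH"),
                    stringsAsFactors = FALSE)
  if (!is.null(D)) {
    out$p_distance <- p_dist
    out$q_distance <- stats::p.adjust(p_dist, method = "BH")
  }
  rownames(out) <- NULL
  out
}
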
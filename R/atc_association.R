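#' Hypergeometric overrepresentation of ATC categories in BAM clusters
#'
#' For each (cluster, category) pair the p-value is the hypergeometric upper
#' tail: the probability of observing `k` or more drugs of the category among
#' the `n` drugs of the cluster, drawn from the population of all `N`
#' training drugs of which `K` hold the category. Significance is called at
#' the nominal `alpha` with no multiplicity correction (a Benjamini-Hochberg
#' column is emitted alongside for reference). For significant pairs, the
#' signature subgroup (cluster members holding the category) and, when
#' Pheno-Prints are supplied, its centroid are extracted.
#'
#' @param assignment a [cut_clusters()] result over the training drugs.
#' @param drug_table drug table with `compound_id`, `atc_codes`
#'   (semicolon-separated level-2 codes) and `set`.
#' @param alpha nominal significance level (default 0.05).
#' @param multi_atc `"all"` (a drug counts toward every category it holds,
#'   default) or `"primary"` (first listed code only).
#' @param phenoprints optional Pheno-Print matrix for signature centroids.
#' @return A list of class `association_result`: `table` (data frame with
#'   `cluster`, `category`, `N`, `K`, `n`, `k`, `p`, `p_bh`, `significant`)
#'   and `signatures` (list with `cluster`, `category`, `p`, `drugs`,
#'   `centroid` per significant pair).
#' @export
hypergeom_overrep <- function(assignment, drug_table, alpha = 0.05,
                              multi_atc = c("all", "primary"),
                              phenoprints = NULL) {
  multi_atc <- match.arg(multi_atc)
  labels <- assignment$labels
  train <- drug_table[drug_table$set == "training", , drop = FALSE]
  if (!all(train$compound_id %in% names(labels))) {
    stop("every training drug must have a cluster label", call. = FALSE)
  }
  codes <- strsplit(train$atc_codes, ";", fixed = TRUE)
  if (multi_atc == "primary") codes <- lapply(codes, function(x) x[1L])
  codes <- lapply(codes, function(x) unique(x[nzchar(x)]))
  names(codes) <- train$compound_id
  categories <- sort(unique(unlist(codes)))
  if (!length(categories)) stop("training drugs carry no ATC codes", call. = FALSE)

  N <- nrow(train)
  clusters <- sort(unique(labels[train$compound_id]))
  holders_by_cat <- lapply(categories, function(cat) {
    train$compound_id[vapply(codes[train$compound_id],
                             function(x) cat %in% x, TRUE)]
  })
  names(holders_by_cat) <- categories
  rows <- list()
  sigs <- list()
  for (cl in clusters) {
    members <- intersect(train$compound_id, names(labels)[labels == cl])
    n <- length(members)
    for (cat in categories) {
      holders <- holders_by_cat[[cat]]
      K <- length(holders)
      overlap <- intersect(members, holders)
      k <- length(overlap)
      if (n == 0L || K == 0L) {
        message("empty cluster or category for pair (", cl, ", ", cat,
                "); p = 1")
        p <- 1
      } else {
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, category = cat, N = N, K = K, n = n, k = k, p = p,
        stringsAsFactors = FALSE)
      if (p < alpha && k > 0L) {
        sigs[[length(sigs) + 1L]] <- list(
          cluster = cl, category = cat, p = p, drugs = overlap,
          centroid = if (!is.null(phenoprints)) {
            signature_centroid(overlap, phenoprints)
          } else {
            NULL
          })
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_bh <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p < alpha
  structure(list(table = tab, signatures = sigs, alpha = alpha),
            class = "association_result")
}

#' Centroid of a signature subgroup in Pheno-Print space
#'
#' @param drug_ids member compound ids (non-empty).
#' @param phenoprints Pheno-Print matrix with rows named by compound id.
#' @return Componentwise mean Pheno-Print (numeric vector).
#' @export
signature_centroid <- function(drug_ids, phenoprints) {
  if (!length(drug_ids)) stop("subgroup is empty", call. = FALSE)
  missing <- setdiff(drug_ids, rownames(phenoprints))
  if (length(missing)) {
    stop("no Pheno-Print for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(phenoprints[drug_ids, , drop = FALSE])
}
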
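#' Train the random-forest cluster classifier
#'
#' Standard random forest (bootstrap per tree, `floor(sqrt(d))` candidate
#' features per split, majority vote) on training Pheno-Prints with the
#' consensus-cluster labels as classes; `ntree = 100` by default. Training is
#' deterministic given the seed, and out-of-bag accuracy is reported.
#'
#' @param phenoprints training Pheno-Print matrix (rows named by drug id).
#' @param assignment a [cut_clusters()] result (or named label vector).
#' @param n_trees ensemble size (default 100).
#' @param seed integer seed.
#' @return A list of class `forest_model`: `forest` (randomForest object),
#'   `classes`, `oob_accuracy`, `n_trees`, `seed`.
#' @export
train_forest <- function(phenoprints, assignment, n_trees = 100L, seed = 1L) {
  labels <- if (inherits(assignment, "cluster_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  x <- phenoprints[names(labels), , drop = FALSE]
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  }
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees))
  oob <- mean(fit$predicted == y)
  if (oob < 1) {
    message(sprintf("out-of-bag accuracy %.3f (< 1): classes overlap", oob))
  }
  structure(list(forest = fit, classes = levels(y), oob_accuracy = oob,
                 n_trees = n_trees, seed = seed),
            class = "forest_model")
}

#' Classify compounds into BAM clusters
#'
#' Majority vote over the ensemble; vote ties are broken toward the lowest
#' cluster label (logged). Test Pheno-Prints must be derived with the
#' training-set PC model.
#'
#' @param model a [train_forest()] result.
#' @param phenoprints Pheno-Print matrix of the compounds to classify.
#' @return Data frame: `compound_id`, `cluster` (integer), and one
#'   `vote_<class>` fraction column per class (fractions sum to 1 per row).
#' @export
classify_compounds <- function(model, phenoprints) {
  stopifnot(inherits(model, "forest_model"))
  x <- as.matrix(phenoprints)
  if (ncol(x) != nrow(model$forest$importance)) {
    stop("feature dimension mismatch with the trained forest", call. = FALSE)
  }
  votes <- stats::predict(model$forest, x, type = "vote", norm.votes = TRUE)
  cls_order <- order(as.integer(colnames(votes)))
  votes <- votes[, cls_order, drop = FALSE]
  assigned <- apply(votes, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1L) {
      message("vote tie broken toward the lowest cluster label")
    }
    as.integer(colnames(votes)[top[1L]])
  })
  out <- data.frame(compound_id = rownames(x), cluster = assigned,
                    stringsAsFactors = FALSE)
  vf <- as.data.frame(votes)
  names(vf) <- paste0("vote_", colnames(votes))
  rownames(out) <- NULL
  cbind(out, vf)
}

#' Rank classified compounds by therapeutic potential
#'
#' Compounds assigned to ATC-associated clusters are scored by the Pearson
#' correlation between their Pheno-Print and the signature subgroup's
#' centroid (the cluster's most significant association is used), and ranked
#' in descending order within each cluster. Compounds in non-associated
#' clusters carry no score; zero-variance Pheno-Prints get a missing score
#' and are ranked last (logged).
#'
#' @param assignments a [classify_compounds()] data frame.
#' @param phenoprints Pheno-Print matrix of the same compounds.
#' @param association a [hypergeom_overrep()] result with centroids.
#' @return Data frame: `compound_id`, `cluster`, `category` (associated ATC
#'   category or `NA`), `r` (Pearson correlation or `NA`), `rank` (within-
#'   cluster rank or `NA`).
#' @export
rank_candidates <- function(assignments, phenoprints, association) {
  stopifnot(inherits(association, "association_result"))
  sigs <- association$signatures
  if (length(sigs) && is.null(sigs[[1]]$centroid)) {
    stop("association result lacks signature centroids; ",
         "pass `phenoprints` to hypergeom_overrep()", call. = FALSE)
  }
  # most significant association per cluster
  best <- list()
  for (s in sigs) {
    key <- as.character(s$cluster)
    if (is.null(best[[key]]) || s$p < best[[key]]$p) best[[key]] <- s
  }
  out <- data.frame(compound_id = assignments$compound_id,
                    cluster = assignments$cluster,
                    category = NA_character_, r = NA_real_, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  for (cl in unique(out$cluster)) {
    s <- best[[as.character(cl)]]
    if (is.null(s)) next
    rows <- which(out$cluster == cl)
    out$category[rows] <- s$category
    r <- vapply(rows, function(i) {
      pp <- phenoprints[out$compound_id[i], ]
      if (stats::sd(pp) == 0 || stats::sd(s$centroid) == 0) {
        message("zero-variance Pheno-Print for ", out$compound_id[i],
                "; correlation undefined, ranked last")
        return(NA_real_)
      }
      stats::cor(pp, s$centroid)
    }, 0)
    out$r[rows] <- r
    out$rank[rows] <- rank(-replace(r, is.na(r), -Inf), ties.method = "first")
  }
  out
}
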
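#' Fit the Pheno-Print PCA basis on a library of T-score BAMs
#'
#' Principal component analysis of the mean-centered, flattened (template-
#' masked) T-score maps, with no variance scaling: T-scores already share a
#' unitless scale. The top `n_components` components (default 20) define the
#' Pheno-Print space. Loading signs follow a deterministic convention — each
#' component's largest-magnitude entry is positive — so Pheno-Prints are
#' reproducible across runs and platforms.
#'
#' @param tscore_bams named list of T-score matrices sharing one grid, or an
#'   `n x p` matrix of already-flattened maps (rows = compounds).
#' @param n_components number of retained components (default 20); must not
#'   exceed the library size.
#' @param mask logical matrix selecting the ROIs to use (default: ROIs finite
#'   in every map).
#' @return A list of class `pc_model`: `mean` (masked mean map vector),
#'   `loadings` (`n_components x n_masked_rois`, orthonormal rows),
#'   `evr` (explained-variance fraction per retained component),
#'   `n_components`, `mask`, `grid`.
#' @export
fit_pca <- function(tscore_bams, n_components = 20L, mask = NULL) {
  if (is.list(tscore_bams)) {
    grid <- dim(tscore_bams[[1]])
    if (is.null(mask)) {
      mask <- Reduce(`&`, lapply(tscore_bams, is.finite))
    }
    x <- do.call(rbind, lapply(tscore_bams, function(m) m[mask]))
    rownames(x) <- names(tscore_bams)
  } else {
    x <- as.matrix(tscore_bams)
    grid <- c(1L, ncol(x))
    if (is.null(mask)) mask <- matrix(TRUE, 1L, ncol(x))
  }
  n <- nrow(x)
  if (n < n_components) {
    stop("library has ", n, " maps but ", n_components,
         " components were requested; lower `n_components`", call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (sum(xc^2) < 1e-12) {
    stop("degenerate library: all maps are identical (zero variance)",
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- t(pc$rotation[, seq_len(k), drop = FALSE])  # k x p
  dimnames(load) <- NULL
  # deterministic sign: largest-|value| entry of each loading is positive
  for (i in seq_len(k)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean = ctr, loadings = load, evr = evr[seq_len(k)],
                 evr_all = evr, n_components = k, mask = mask, grid = grid),
            class = "pc_model")
}

#' Project a T-score BAM into Pheno-Print space
#'
#' Coefficients of the mean-centered, masked map on the model's orthonormal
#' loadings. Test-set compounds must always be projected with the
#' training-set model.
#'
#' @param map T-score matrix on the model's grid (or an already-flattened
#'   masked vector).
#' @param model a [fit_pca()] result.
#' @return Numeric coefficient vector of length `model$n_components`, named
#'   `pc1..pcK`.
#' @export
project_phenoprint <- function(map, model) {
  stopifnot(inherits(model, "pc_model"))
  if (is.matrix(map) && !is.null(dim(model$mask)) &&
      all(dim(map) == dim(model$mask))) {
    v <- map[model$mask]
  } else if (length(map) == length(model$mean)) {
    v <- as.numeric(map)
  } else {
    stop("map does not match the model's mask", call. = FALSE)
  }
  coef <- as.numeric(model$loadings %*% (v - model$mean))
  stats::setNames(coef, paste0("pc", seq_along(coef)))
}

#' Project a library of T-score BAMs
#'
#' @param tscore_bams named list of T-score matrices.
#' @param model a [fit_pca()] result.
#' @return `n x n_components` matrix of Pheno-Prints (rows named by drug id).
#' @export
project_library <- function(tscore_bams, model) {
  out <- t(vapply(tscore_bams, project_phenoprint, model = model,
                  numeric(model$n_components)))
  colnames(out) <- paste0("pc", seq_len(model$n_components))
  out
}

#' Reconstruct a T-score BAM from a Pheno-Print
#'
#' `mean + loadings' * coefficients`, re-embedded into the template mask
#' (`NA` outside).
#'
#' @param phenoprint coefficient vector of length `model$n_components`.
#' @param model a [fit_pca()] result.
#' @return Reconstructed map matrix on the model's grid.
#' @export
reconstruct_map <- function(phenoprint, model) {
  stopifnot(inherits(model, "pc_model"))
  if (length(phenoprint) != model$n_components) {
    stop("coefficient length ", length(phenoprint), " != n_components ",
         model$n_components, call. = FALSE)
  }
  v <- model$mean + as.numeric(crossprod(model$loadings, phenoprint))
  out <- matrix(NA_real_, model$grid[1], model$grid[2])
  out[model$mask] <- v
  out
}
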
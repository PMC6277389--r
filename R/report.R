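#' Render the report bundle for a pipeline run
#'
#' Emits the consensus heatmap, the CDF/AUC curves for the candidate cluster
#' numbers, a gallery of representative cluster patterns, the cluster-by-ATC
#' association heatmap, the ranked-candidate tables, a DMSO control panel and
#' a plain-text run summary. Panels whose stage output is missing are skipped
#' with a notice.
#'
#' @param run a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return Character vector of written file paths (invisibly from
#'   [run_pipeline()]).
#' @export
render_report <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  skip <- function(panel) message("report: missing stage output; skipping ", panel)

  pal <- grDevices::hcl.colors(64, "Blue-Red 3")

  if (!is.null(run$consensus) && !is.null(run$k_selected)) {
    M <- run$consensus$M[[as.character(run$k_selected)]]
    ord <- order(run$assignment$labels)
    f <- file.path(out_dir, "consensus_heatmap.png")
    grDevices::png(f, 800, 800)
    graphics::image(M[ord, rev(ord)], col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                    axes = FALSE, main = sprintf("Consensus matrix (k = %d)", run$k_selected))
    grDevices::dev.off()
    files <- c(files, f)

    f <- file.path(out_dir, "consensus_auc.png")
    grDevices::png(f, 700, 500)
    graphics::plot(run$consensus$k_range, run$consensus$auc, type = "b",
                   xlab = "k", ylab = "AUC of consensus CDF",
                   main = "Cluster-number selection (AUC-CDF rule)")
    graphics::abline(v = run$k_selected, lty = 2)
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    skip("consensus panels")
  }

  if (!is.null(run$assignment$patterns)) {
    k <- run$assignment$k
    f <- file.path(out_dir, "cluster_patterns.png")
    nc <- ceiling(sqrt(k))
    grDevices::png(f, 250 * nc, 250 * ceiling(k / nc))
    graphics::par(mfrow = c(ceiling(k / nc), nc), mar = c(1, 1, 2, 1))
    lim <- max(abs(unlist(run$assignment$patterns)), na.rm = TRUE)
    for (cl in seq_len(k)) {
      graphics::image(t(run$assignment$patterns[[cl]])[, nrow(run$assignment$patterns[[cl]]):1],
                      zlim = c(-lim, lim), col = pal, axes = FALSE,
                      main = sprintf("cluster %d (n = %d)", cl,
                                     sum(run$assignment$labels == cl)))
    }
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    skip("cluster pattern gallery")
  }

  if (!is.null(run$association)) {
    tab <- run$association$table
    cls <- sort(unique(tab$cluster))
    cats <- sort(unique(tab$category))
    pm <- matrix(1, length(cls), length(cats), dimnames = list(cls, cats))
    for (i in seq_len(nrow(tab))) {
      pm[as.character(tab$cluster[i]), tab$category[i]] <- tab$p[i]
    }
    f <- file.path(out_dir, "association_heatmap.png")
    grDevices::png(f, 700, 600)
    graphics::image(seq_along(cls), seq_along(cats), -log10(pm),
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                    xlab = "BAM cluster", ylab = "", axes = FALSE,
                    main = "Cluster x ATC association (-log10 p)")
    graphics::axis(1, at = seq_along(cls), labels = cls)
    graphics::axis(2, at = seq_along(cats), labels = cats, las = 2)
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    skip("association heatmap")
  }

  if (!is.null(run$predictions)) {
    ranked <- run$predictions[!is.na(run$predictions$r), , drop = FALSE]
    ranked <- ranked[order(ranked$cluster, ranked$rank), , drop = FALSE]
    f <- file.path(out_dir, "ranked_candidates.csv")
    utils::write.csv(ranked, f, row.names = FALSE)
    files <- c(files, f)
  } else {
    skip("ranked candidate tables")
  }

  if (!is.null(run$tscores) && "DMSO" %in% names(run$tscores) &&
      !is.null(run$assignment$patterns)) {
    f <- file.path(out_dir, "dmso_control.png")
    grDevices::png(f, 500, 300)
    dmso_t <- run$tscores[["DMSO"]]
    drug_mean <- mean(vapply(run$assignment$patterns,
                             function(p) mean(abs(p), na.rm = TRUE), 0))
    graphics::barplot(c(DMSO = mean(abs(dmso_t)), drugs = drug_mean),
                      ylab = "mean |T|",
                      main = "Control vs drug T-score magnitude")
    grDevices::dev.off()
    files <- c(files, f)
  }

  f <- file.path(out_dir, "run_summary.txt")
  lines <- c(
    "bamscope run summary",
    sprintf("training drugs: %d", run$config$scenario$n_train_drugs),
    sprintf("test compounds: %d", run$config$scenario$n_test_drugs),
    if (!is.null(run$k_selected)) sprintf("selected k: %d", run$k_selected),
    if (!is.null(run$association)) {
      sprintf("significant cluster/ATC pairs: %d",
              sum(run$association$table$significant))
    },
    if (!is.null(run$forest)) {
      sprintf("forest OOB accuracy: %.3f", run$forest$oob_accuracy)
    })
  writeLines(lines, f)
  files <- c(files, f)
  files
}
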
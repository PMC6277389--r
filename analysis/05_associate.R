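#!/usr/bin/env Rscript
# Cluster/ATC association: hypergeometric upper-tail test for every
# (BAM cluster, ATC category) pair at nominal alpha = 0.05, with signature
# subgroups and their Pheno-Print centroids for the significant pairs.

source(file.path("analysis", "00_common.R"))

lib <- cached("library", simulate_bam_library(scenario_config(seed = SEED)))
pp <- cached("pp_train", stop("run analysis/03_phenoprint.R first"))
assignment <- cached("assignment", stop("run analysis/04_cluster.R first"))

assoc <- cached("association",
  hypergeom_overrep(assignment, lib$drug_table, alpha = 0.05,
                    phenoprints = pp))

write.csv(assoc$table, file.path(RESULTS, "association.csv"),
          row.names = FALSE)
sig <- assoc$table[assoc$table$significant, ]
cat(sprintf("%d of %d (cluster, category) pairs significant at p < 0.05:\n",
            nrow(sig), nrow(assoc$table)))
print(sig[order(sig$p), c("cluster", "category", "N", "K", "n", "k", "p")],
      digits = 3, row.names = FALSE)

cat("\nsignature subgroup sizes:\n")
for (s in assoc$signatures) {
  cat(sprintf("  cluster %d x %s: %d drugs (p = %.2e)\n",
              s$cluster, s$category, length(s$drugs), s$p))
}
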
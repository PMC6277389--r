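#!/usr/bin/env Rscript
# Functional prediction of the 121 unlabeled test compounds: train the
# 100-tree random forest on the training Pheno-Prints and consensus labels,
# classify the test compounds into BAM clusters, rank candidates in
# ATC-associated clusters by Pearson correlation to the signature centroid,
# and measure re-acquisition reproducibility on 20 re-simulated compounds.

source(file.path("analysis", "00_common.R"))

lib <- cached("library", simulate_bam_library(scenario_config(seed = SEED)))
model <- cached("pc_model", stop("run analysis/03_phenoprint.R first"))
pp <- cached("pp_train", stop("run analysis/03_phenoprint.R first"))
pp_test <- cached("pp_test", stop("run analysis/03_phenoprint.R first"))
assignment <- cached("assignment", stop("run analysis/04_cluster.R first"))
assoc <- cached("association", stop("run analysis/05_associate.R first"))

forest <- train_forest(pp, assignment, n_trees = 100,
                       seed = derive_seed(SEED, "forest"))
cat(sprintf("random forest (100 trees): OOB accuracy %.3f\n",
            forest$oob_accuracy))

cls <- classify_compounds(forest, pp_test)
pred <- rank_candidates(cls, pp_test, assoc)
write.csv(pred, file.path(RESULTS, "predictions.csv"), row.names = FALSE)

scored <- pred[!is.na(pred$r), ]
cat(sprintf("%d of %d test compounds fall in ATC-associated clusters\n",
            nrow(scored), nrow(pred)))
top <- scored[scored$rank <= 3, ]
cat("top-3 candidates per associated cluster:\n")
print(top[order(top$cluster, top$rank), ], digits = 3, row.names = FALSE)
cat(sprintf("correlation band of top-decile candidates: %.2f-%.2f\n",
            min(scored$r[scored$rank <= 3]), max(scored$r[scored$rank <= 3])))

# re-acquisition reproducibility (20 compounds, fresh replicates)
set.seed(derive_seed(SEED, "pick"))
picked <- sample(rownames(pp_test), 20)
reacq <- resimulate_replicates(lib, picked,
                               seed = derive_seed(SEED, "reacquire"))
pp2 <- project_library(lapply(reacq, compute_tscore_bam), model)
second <- classify_compounds(forest, pp2)
agree <- mean(cls$cluster[match(picked, cls$compound_id)] == second$cluster)
cat(sprintf("re-acquisition: %.0f%% of 20 compounds assigned to the same cluster\n",
            100 * agree))
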
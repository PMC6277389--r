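#!/usr/bin/env Rscript
# T-score BAMs and Pheno-Prints: compute the replicate T statistic per ROI
# for every compound, fit the 20-component PCA basis on the training
# library, and project training and test maps into Pheno-Print space.

source(file.path("analysis", "00_common.R"))

lib <- cached("library", simulate_bam_library(scenario_config(seed = SEED)))
tab <- lib$drug_table
train_ids <- tab$compound_id[tab$set == "training"]
test_ids <- tab$compound_id[tab$set == "test"]

tscores <- cached("tscores", tscore_library(lib))
model <- cached("pc_model", fit_pca(tscores[train_ids], n_components = 20))
pp <- cached("pp_train", project_library(tscores[train_ids], model))
pp_test <- cached("pp_test", project_library(tscores[test_ids], model))

evr <- data.frame(component = seq_along(model$evr),
                  explained_variance = model$evr,
                  cumulative = cumsum(model$evr))
write.csv(evr, file.path(RESULTS, "pca_variance.csv"), row.names = FALSE)
cat(sprintf("top-20 PCs explain %.1f%% of the T-score BAM variance\n",
            100 * sum(model$evr)))

all_pp <- rbind(pp, pp_test)
write.csv(data.frame(compound_id = rownames(all_pp), all_pp, row.names = NULL),
          file.path(RESULTS, "phenoprints.csv"), row.names = FALSE)
cat(sprintf("wrote %d Pheno-Prints (%d training, %d test)\n",
            nrow(all_pp), nrow(pp), nrow(pp_test)))

# DMSO control: white-noise-like T-score maps
dmso_t <- tscores[["DMSO"]]
cat(sprintf("mean |T|: DMSO %.2f vs drugs %.2f\n",
            mean(abs(dmso_t)),
            mean(vapply(tscores[train_ids[1:20]],
                        function(m) mean(abs(m)), 0))))
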